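test_that("fork direction convention sets strand by side of the origin", {
  g <- tiny_genome(L = 200000L)
  m <- single_origin_model(position = 100000L, fork_speed = 80000)
  sim <- simulate_break_sites(m, g, n_cells = 3000L, seed = 42)
  s <- sim$sites
  right <- s[s$position > 100000, ]
  left <- s[s$position < 100000, ]
  expect_true(nrow(right) > 500 && nrow(left) > 500)
  # rightward forks (right of origin) are reverse; leftward forks forward
  expect_equal(mean(right$strand == "-"), 1)
  expect_equal(mean(left$strand == "+"), 1)
})

test_that("origin efficiency behaves as an independent Bernoulli trial", {
  g <- tiny_genome(L = 200000L)
  m <- fork_model(data.frame(position = 100000L, efficiency = 0.5,
                             firing_time = 0), fork_speed = 50000)
  n_cells <- 10000L
  sim <- simulate_break_sites(m, g, n_cells, seed = 7)
  frac <- length(unique(sim$sites$cell)) / n_cells
  # 0.5 within 4 binomial standard errors
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / n_cells))
})

test_that("stall residence weight multiplies window density as the time-grid oracle predicts", {
  w <- 9
  stall_win <- c(34750, 35250)   # 500 bp zone centred on the stall
  match_win <- c(29750, 30250)   # matched 500 bp window on the same fork path
  x0 <- 25000; t0 <- 0.1; v <- 20000
  # brute-force oracle: enumerate observation times on a fine grid; a
  # rightward fork sits in a window while x0 + v*(T-t0) is inside it, and is
  # observed with probability (1+w)/(1+w) inside the stall, 1/(1+w) outside
  grid <- seq(0, 1, length.out = 200001)
  posn <- x0 + v * pmax(0, grid - t0)
  alive <- grid >= t0
  exp_stall <- sum(alive & posn >= stall_win[1] & posn < stall_win[2]) * 1
  exp_match <- sum(alive & posn >= match_win[1] & posn < match_win[2]) / (1 + w)
  oracle_ratio <- exp_stall / exp_match
  expect_equal(oracle_ratio, 10, tolerance = 0.01)

  g <- tiny_genome(L = 50000L)
  m <- fork_model(data.frame(position = x0, efficiency = 1, firing_time = t0),
                  fork_speed = v,
                  stall_sites = data.frame(position = 35000, width = 500,
                                           direction = "rightward",
                                           residence_weight = w))
  sim <- simulate_break_sites(m, g, n_cells = 60000L, seed = 13)
  s <- sim$sites[sim$sites$strand == "-", ]
  n_stall <- sum(s$position >= stall_win[1] & s$position < stall_win[2])
  n_match <- sum(s$position >= match_win[1] & s$position < match_win[2])
  ratio <- n_stall / n_match
  se <- ratio * sqrt(1 / n_stall + 1 / n_match)
  expect_lt(abs(ratio - oracle_ratio), 4 * se)
})

test_that("a model with no firing origins and no background refuses to emit", {
  g <- tiny_genome(L = 10000L)
  m <- fork_model(data.frame(position = 5000L, efficiency = 0,
                             firing_time = 0.1), fork_speed = 1000)
  expect_error(simulate_break_sites(m, g, 10L), "no signal")
})

test_that("simulation is byte-identical under a fixed seed", {
  g <- tiny_genome()
  m <- fork_model(data.frame(position = 25000L, efficiency = 0.8,
                             firing_time = 0.2), fork_speed = 20000,
                  background_break_rate = 1e-5)
  s1 <- simulate_break_sites(m, g, 800L, seed = 3)
  s2 <- simulate_break_sites(m, g, 800L, seed = 3)
  expect_identical(s1$sites, s2$sites)
})

test_that("read emission follows the UMI + poly-T + genomic structure", {
  g <- tiny_genome()
  sites <- data.frame(chrom = "chr1",
                      position = c(25000L, 26000L),
                      strand = c("+", "-"))
  er <- emit_reads(sites, g, read_length = 60L, pcr_duplication_rate = 0,
                   seed = 2)
  expect_equal(nrow(er$reads), 2L)              # no duplication: one per molecule
  expect_true(all(nchar(er$reads$sequence) == 60L))
  chr <- as.character(g$seq[["chr1"]])
  for (i in 1:2) {
    tr <- er$truth[i, ]
    expect_identical(substr(er$reads$sequence[i], 1, 8), tr$umi)
    body <- substr(er$reads$sequence[i], 9 + tr$polyT, 60)
    glen <- 60L - 8L - tr$polyT
    if (tr$strand == "+") {
      expect_identical(body, substr(chr, tr$position + 1, tr$position + glen))
    } else {
      span <- substr(chr, tr$position + 2 - glen, tr$position + 1)
      expect_identical(body, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(span))))
    }
  }
})

test_that("PCR duplicates are exact copies at the configured rate", {
  g <- tiny_genome()
  sites <- data.frame(chrom = "chr1",
                      position = rep(20000:20999, length.out = 1000L),
                      strand = "+")
  er <- emit_reads(sites, g, pcr_duplication_rate = 0.5, seed = 8)
  n_rec <- nrow(er$reads)
  # 1000 molecules, one extra copy each with p = 0.5
  expect_lt(abs(n_rec - 1500), 4 * sqrt(1000 * 0.25))
  expect_equal(n_rec, sum(er$truth$n_records))
  # duplicates introduce no new (position, strand, UMI) triples
  dup_ids <- sub("\\.2$", "", er$reads$read_id[grepl("\\.2$", er$reads$read_id)])
  expect_true(all(dup_ids %in% sub("\\.1$", "",
                                   er$reads$read_id[grepl("\\.1$", er$reads$read_id)])))
  dup_seq <- er$reads$sequence[match(paste0(dup_ids, ".2"), er$reads$read_id)]
  orig_seq <- er$reads$sequence[match(paste0(dup_ids, ".1"), er$reads$read_id)]
  expect_identical(dup_seq, orig_seq)
})

test_that("molecules too close to the contig edge are truncated and flagged", {
  g <- tiny_genome(L = 1000L)
  sites <- data.frame(chrom = "chr1", position = c(990L, 10L, 500L),
                      strand = c("+", "-", "+"))
  er <- emit_reads(sites, g, read_length = 60L, seed = 4)
  expect_identical(er$truth$truncated, c(TRUE, TRUE, FALSE))
  expect_lt(nchar(er$reads$sequence[1]), 60L)
})
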