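fake_aln <- function(pos, strand, umi, id = NULL) {
  n <- length(pos)
  data.frame(read_id = if (is.null(id)) sprintf("r%03d:%s", seq_len(n), umi)
             else id,
             umi = umi, chrom = "chr1",
             start = ifelse(strand == "+", pos, pos - 49L),
             end = ifelse(strand == "+", pos + 50L, pos + 1L),
             strand = strand, mapq = 42L, stringsAsFactors = FALSE)
}

test_that("UMI dedup keys on chromosome, 5' position, orientation and UMI", {
  a <- fake_aln(rep(1000L, 5), rep("+", 5), rep("AAAAAAAA", 5))
  d <- umi_dedup(a)
  expect_equal(nrow(d), 1L)
  expect_equal(attr(d, "n_duplicates"), 4L)

  b <- fake_aln(rep(1000L, 2), rep("+", 2), c("AAAAAAAA", "CCCCCCCC"))
  expect_equal(nrow(umi_dedup(b)), 2L)

  # same position, opposite strands: distinct keys
  c2 <- fake_aln(rep(1000L, 2), c("+", "-"), rep("AAAAAAAA", 2))
  expect_equal(nrow(umi_dedup(c2)), 2L)

  # unparseable UMI rejected and counted
  e <- fake_aln(c(10L, 20L) + 100L, c("+", "+"), c("AAAA", "ACGTACGT"))
  de <- umi_dedup(e)
  expect_equal(nrow(de), 1L)
  expect_equal(attr(de, "n_rejected"), 1L)
})

test_that("UMI dedup is idempotent, order-insensitive and matches a brute-force oracle", {
  g <- tiny_genome(L = 80000L)
  m <- single_origin_model(position = 40000L, fork_speed = 30000)
  sim <- simulate_break_sites(m, g, 1500L, seed = 51)
  er <- emit_reads(sim$sites, g, pcr_duplication_rate = 0.5, seed = 52)
  aln <- align_reads(trim_polyT(extract_umi(er$reads)), g)

  d1 <- umi_dedup(aln)
  d2 <- umi_dedup(d1)
  expect_equal(d2[names(d1)], d1[names(d1)])
  shuf <- aln[sample.int(nrow(aln)), ]
  d3 <- umi_dedup(shuf)
  expect_equal(d3[c("chrom", "start", "end", "strand", "umi")],
               d1[c("chrom", "start", "end", "strand", "umi")])

  # brute-force oracle over all truth fields
  oracle <- length(unique(paste(er$truth$chrom, er$truth$position,
                                er$truth$strand, er$truth$umi)))
  expect_equal(nrow(d1), oracle)
  expect_equal(nrow(d1), nrow(er$truth))  # no UMI collisions at this scale
})

test_that("truncation to the break keeps the 5'-most base in read orientation", {
  a <- data.frame(read_id = c("f:AAAAAAAA", "r:AAAAAAAA"),
                  umi = "AAAAAAAA", chrom = "chr1",
                  start = c(100L, 100L), end = c(150L, 150L),
                  strand = c("+", "-"), mapq = 42L)
  b <- truncate_to_break(a)
  expect_equal(b$position, c(100L, 149L))
  expect_equal(b$strand, c("+", "-"))
})

test_that("running-window counts match exhaustive containment", {
  # one site at 25: windows of 50 bp every 10 bp starting at 0, 10, 20
  tr <- count_windows(data.frame(chrom = "chr1", position = 25L, strand = "+"),
                      c(chr1 = 200L), window_size = 50L, step = 10L)
  hits <- tr$start[tr$fwd > 0]
  oracle <- Filter(function(s) 25 >= s && 25 < s + 50, seq(0, 190, 10))
  expect_equal(hits, as.integer(oracle))
  expect_equal(hits, c(0L, 10L, 20L))

  # property over random sites: site in window iff start <= p < start + w
  set.seed(77)
  pos <- sample.int(500L, 60L) - 1L
  tr2 <- count_windows(data.frame(chrom = "chr1", position = pos,
                                  strand = "+"),
                       c(chr1 = 500L), window_size = 35L, step = 10L)
  for (k in sample.int(nrow(tr2), 10L)) {
    expect_equal(tr2$fwd[k],
                 sum(pos >= tr2$start[k] & pos < tr2$start[k] + 35L))
  }
})

test_that("partitioning windows conserve total site count; empty input gives zero track", {
  set.seed(8)
  pos <- sample.int(1000L, 200L, replace = TRUE) - 1L
  st <- sample(c("+", "-"), 200L, TRUE)
  tr <- count_windows(data.frame(chrom = "chr1", position = pos, strand = st),
                      c(chr1 = 1000L), window_size = 50L, step = 50L)
  expect_equal(sum(tr$fwd) + sum(tr$rev), 200)

  e <- count_windows(data.frame(chrom = character(), position = numeric(),
                                strand = character()),
                     c(chr1 = 1000L), 50L, 10L)
  expect_true(all(e$fwd == 0) && all(e$rev == 0))
})

test_that("blacklist filtering excludes exactly the overlapping windows", {
  tr <- random_track(n = 100L, seed = 10L, L = 2000L)
  # full-chromosome interval excludes everything
  all_out <- filter_blacklist(tr, data.frame(chrom = "chr1", start = 0L,
                                             end = 2000L))
  expect_false(any(all_out$included))
  # empty blacklist is the identity
  expect_identical(filter_blacklist(tr, NULL)$included, tr$included)
  # single 1-bp interval in the interior: ceil(window/step) windows excluded
  one <- filter_blacklist(tr, data.frame(chrom = "chr1", start = 1000L,
                                         end = 1001L))
  excluded <- which(!one$included)
  oracle <- which(vapply(seq_len(nrow(tr)), function(k) {
    tr$start[k] < 1001L && 1000L < tr$end[k]
  }, logical(1)))
  expect_equal(excluded, oracle)
  expect_equal(length(excluded), ceiling(50L / 10L))
})

test_that("RPM normalisation scales included windows to one million total", {
  tr <- random_track(n = 500L, seed = 12L, L = 5000L)
  tr <- filter_blacklist(tr, data.frame(chrom = "chr1", start = 0L,
                                        end = 500L))
  raw_excl <- tr$fwd[!tr$included]
  rpm <- normalize_rpm(tr)
  inc <- rpm$included
  expect_equal(sum(rpm$fwd[inc]) + sum(rpm$rev[inc]), 1e6)
  expect_equal(rpm$fwd[!inc], raw_excl)   # excluded untouched
  expect_error(normalize_rpm(rpm), "already normalized")

  zero <- random_track(n = 10L, seed = 13L, L = 500L)
  zero$fwd[] <- 0; zero$rev[] <- 0
  expect_error(normalize_rpm(zero), "zero total")
})

test_that("enrichment normalisation removes pure scale differences", {
  tr <- random_track(n = 800L, seed = 14L, L = 3000L)
  a <- normalize_rpm(tr)
  b <- a; b$fwd <- b$fwd * 2; b$rev <- b$rev * 2
  attr(b, "norm") <- "rpm"
  nn <- normalize_enrichment(list(a, b))
  # identical shapes: post-normalisation tracks equal
  expect_equal(nn[[1]]$fwd, nn[[2]]$fwd, tolerance = 1e-10)
  expect_equal(nn[[1]]$rev, nn[[2]]$rev, tolerance = 1e-10)
  # two identical tracks: factors exactly 1
  n2 <- normalize_enrichment(list(a, a))
  expect_equal(attr(n2[[1]], "enrichment_factor"), 1)
  expect_equal(attr(n2[[2]], "enrichment_factor"), 1)
  # polarity unchanged by the rescaling
  p_a <- compute_polarity(a)$polarity
  p_n <- compute_polarity(nn[[1]])$polarity
  expect_equal(p_n, p_a, tolerance = 1e-12)
})
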