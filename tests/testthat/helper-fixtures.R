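# Shared fixtures, built in code at test time.

# small single-chromosome genome
tiny_genome <- function(L = 50000L, seed = 11L) {
  build_genome(genome_spec(c(chr1 = L), seed = seed))
}

# genome with a tandem repeat array (unit carries no origin; sequence only)
repeat_genome <- function(L = 60000L, unit_len = 2000L, copies = 3L,
                          at = 30000L, seed = 21L) {
  set.seed(seed + 1L)
  unit <- paste(sample(c("A", "C", "G", "T"), unit_len, replace = TRUE),
                collapse = "")
  build_genome(genome_spec(
    c(chr1 = L),
    repeat_arrays = data.frame(chrom = "chr1", position = at, unit = unit,
                               copies = copies),
    seed = seed))
}

# one efficient interior origin; forks never reach the chromosome ends
single_origin_model <- function(position = 25000L, efficiency = 1,
                                firing_time = 0.1, fork_speed = 20000) {
  fork_model(data.frame(position = position, efficiency = efficiency,
                        firing_time = firing_time),
             fork_speed = fork_speed)
}

random_track <- function(n = 50L, seed = NULL, L = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  sites <- data.frame(
    chrom = "chr1",
    position = sample.int(L, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE))
  count_windows(sites, c(chr1 = L), window_size = 50L, step = 10L)
}
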