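#' Emit TrAEL-seq structured reads from break sites
#'
#' Converts break-site molecules into reads with the library structure
#' `NNNNNNNN(T)nSEQUENCESPECIFIC`: an 8 bp unique molecular identifier (UMI),
#' a poly-T stretch of 1-3 bases, then genomic sequence starting at the
#' break-adjacent nucleotide and reading into the fragment in the orientation
#' implied by strand (forward sites read rightward on the top strand; reverse
#' sites read leftward, reported as the reverse complement). Each molecule
#' receives an independent random UMI; PCR duplicates are exact copies (same
#' UMI, same sequence) appended with probability `pcr_duplication_rate` per
#' molecule. Quality strings are constant.
#'
#' @param sites data.frame with `chrom`, `position`, `strand` columns (e.g.
#'   `simulate_break_sites(...)$sites`), one molecule per row.
#' @param genome `trael_genome` or `DNAStringSet`.
#' @param read_length total read length including UMI and poly-T; must be at
#'   least `umi_length + 3 + 20`.
#' @param umi_length UMI length in bp (8 for this library design).
#' @param polyT_range integer vector of allowed poly-T lengths (default 1:3),
#'   sampled uniformly per molecule.
#' @param pcr_duplication_rate probability that a molecule gains one extra
#'   exact PCR copy.
#' @param seed optional integer seed.
#' @return list with `reads` (data.frame `read_id`, `sequence`, `qualities`;
#'   originals first, duplicates appended) and `truth` (one row per molecule:
#'   site coordinates, `umi`, `polyT`, `truncated` flag for molecules closer
#'   to a contig edge than the genomic read span, and `n_records`).
#' @export
emit_reads <- function(sites, genome, read_length = 60L, umi_length = 8L,
                       polyT_range = 1:3, pcr_duplication_rate = 0,
                       seed = NULL) {
  stopifnot(all(c("chrom", "position", "strand") %in% names(sites)))
  if (read_length < umi_length + 3L + 20L)
    stop("read_length must be >= umi_length + 3 + 20")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sites)
  if (!n) stop("no sites to emit")
  seqs <- as_genome_seq(genome)
  lens <- genome_lengths(genome)
  alph <- c("A", "C", "G", "T")

  umi <- vapply(seq_len(n), function(i)
    paste(alph[sample.int(4L, umi_length, replace = TRUE)], collapse = ""),
    character(1))
  nT <- polyT_range[sample.int(length(polyT_range), n, replace = TRUE)]
  g <- read_length - umi_length - nT

  genomic <- character(n)
  truncated <- logical(n)
  for (ch in unique(sites$chrom)) {
    sel <- which(sites$chrom == ch)
    chrstr <- as.character(seqs[[ch]])
    L <- lens[[ch]]
    pos <- sites$position[sel]
    fw <- sites$strand[sel] == "+"
    # forward: read covers [pos, pos + g) on the top strand
    if (any(fw)) {
      i <- sel[fw]
      end1 <- pmin(pos[fw] + g[i], L)
      genomic[i] <- substring(chrstr, pos[fw] + 1L, end1)
      truncated[i] <- end1 < pos[fw] + g[i]
    }
    # reverse: read covers (pos - g, pos] and is reverse-complemented
    if (any(!fw)) {
      i <- sel[!fw]
      start1 <- pmax(pos[!fw] + 2L - g[i], 1L)
      raw <- substring(chrstr, start1, pos[!fw] + 1L)
      genomic[i] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(raw)))
      truncated[i] <- start1 > pos[!fw] + 2L - g[i]
    }
  }

  sequence <- paste0(umi, strrep("T", nT), genomic)
  mol_id <- sprintf("M%07d", seq_len(n))
  dup <- runif(n) < pcr_duplication_rate
  reads <- data.frame(
    read_id = c(paste0(mol_id, ".1"), paste0(mol_id, ".2")[dup]),
    sequence = c(sequence, sequence[dup]),
    stringsAsFactors = FALSE)
  reads$qualities <- strrep("I", nchar(reads$sequence))

  truth <- data.frame(molecule = mol_id, chrom = sites$chrom,
                      position = sites$position, strand = sites$strand,
                      umi = umi, polyT = nT, truncated = truncated,
                      n_records = 1L + dup)
  list(reads = reads, truth = truth)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with `read_id`, `sequence`, `qualities`.
#' @param path output path (`.gz` compressed if the extension says so).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qualities),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path (gzip allowed).
#' @return data.frame with `read_id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             qualities = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}
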