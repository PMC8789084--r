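#' Specify a synthetic reference genome
#'
#' Describes a genome made of random-sequence chromosomes into which tandem
#' repeat arrays (e.g. a multi-copy locus in which every unit carries its own
#' replication origin) can be inserted, together with intervals destined to be
#' masked by Ns. All coordinates are 0-based half-open.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp), or a
#'   named numeric vector of lengths.
#' @param repeat_arrays optional data.frame with columns `chrom`, `position`
#'   (insertion point, coordinates of the repeat-free chromosome), `unit`
#'   (unit sequence, ACGT string) and `copies` (>= 1). Each array inserts
#'   `copies` exact tandem copies of `unit` at `position`, lengthening the
#'   chromosome.
#' @param mask_intervals optional data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open, coordinates of the final built genome).
#' @param seed integer seed controlling the random background sequence.
#' @return object of class `genome_spec`.
#' @seealso [build_genome()]
#' @export
genome_spec <- function(chromosomes, repeat_arrays = NULL, mask_intervals = NULL,
                        seed = 1L) {
  if (!is.data.frame(chromosomes)) {
    chromosomes <- data.frame(name = names(chromosomes),
                              length = as.numeric(chromosomes))
  }
  stopifnot(all(c("name", "length") %in% names(chromosomes)),
            nrow(chromosomes) >= 1L)
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(chromosomes$name)) stop("duplicated chromosome names")

  if (!is.null(repeat_arrays) && nrow(repeat_arrays)) {
    stopifnot(all(c("chrom", "position", "unit", "copies") %in% names(repeat_arrays)))
    if (any(repeat_arrays$copies < 1)) stop("repeat copy number must be >= 1")
    if (!all(repeat_arrays$chrom %in% chromosomes$name))
      stop("repeat array on unknown chromosome")
    len <- setNames(chromosomes$length, chromosomes$name)
    if (any(repeat_arrays$position < 0 |
            repeat_arrays$position > len[repeat_arrays$chrom]))
      stop("repeat insertion position outside chromosome")
    if (any(grepl("[^ACGT]", repeat_arrays$unit)))
      stop("repeat unit sequence must be ACGT only")
    key <- paste(repeat_arrays$chrom, repeat_arrays$position)
    if (anyDuplicated(key)) {
      stop("overlapping repeat insertions at ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    }
  }
  if (!is.null(mask_intervals) && nrow(mask_intervals)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(mask_intervals)))
    if (any(mask_intervals$start >= mask_intervals$end))
      stop("mask intervals need start < end")
  }
  structure(list(chromosomes = chromosomes,
                 repeat_arrays = repeat_arrays,
                 mask_intervals = mask_intervals,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Build a reference genome from a specification
#'
#' Generates the random background sequence deterministically from the spec's
#' seed, inserts each tandem repeat array as exact copies of its unit, and
#' reports per-copy coordinates so that multi-mapping behaviour of reads
#' derived from the array is testable.
#'
#' @param spec a [genome_spec()].
#' @return object of class `trael_genome`: a list with elements `seq`
#'   (a [Biostrings::DNAStringSet]), `chrom_lengths` (named integer vector of
#'   final lengths), `repeats` (data.frame of per-copy 0-based half-open
#'   coordinates in the final genome) and `masks` (the spec's mask intervals).
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  alph <- c("A", "C", "G", "T")
  seqs <- lapply(spec$chromosomes$length, function(L) {
    paste(alph[sample.int(4L, L, replace = TRUE)], collapse = "")
  })
  names(seqs) <- spec$chromosomes$name

  rep_coords <- NULL
  ra <- spec$repeat_arrays
  if (!is.null(ra) && nrow(ra)) {
    ra <- ra[order(ra$chrom, ra$position), , drop = FALSE]
    shift <- setNames(rep(0, nrow(spec$chromosomes)), spec$chromosomes$name)
    out <- vector("list", nrow(ra))
    for (i in seq_len(nrow(ra))) {
      ch <- ra$chrom[i]
      unit <- ra$unit[i]
      k <- ra$copies[i]
      ins0 <- ra$position[i] + shift[ch]   # 0-based insertion point, current coords
      s <- seqs[[ch]]
      insert <- strrep(unit, k)
      seqs[[ch]] <- paste0(substr(s, 1L, ins0), insert,
                           substr(s, ins0 + 1L, nchar(s)))
      ul <- nchar(unit)
      out[[i]] <- data.frame(chrom = ch,
                             start = ins0 + (seq_len(k) - 1L) * ul,
                             end = ins0 + seq_len(k) * ul,
                             array = i, copy = seq_len(k))
      shift[ch] <- shift[ch] + k * ul
    }
    rep_coords <- do.call(rbind, out)
  }

  dna <- Biostrings::DNAStringSet(unlist(seqs))
  g <- structure(list(seq = dna,
                      chrom_lengths = setNames(Biostrings::width(dna), names(dna)),
                      repeats = rep_coords,
                      masks = spec$mask_intervals,
                      spec = spec),
                 class = "trael_genome")
  g
}

#' @export
print.trael_genome <- function(x, ...) {
  cat("trael_genome:", length(x$seq), "chromosome(s),",
      sum(as.numeric(x$chrom_lengths)), "bp total\n")
  if (!is.null(x$repeats)) {
    cat("  repeat copies:", nrow(x$repeats), "\n")
  }
  invisible(x)
}

# Accept either a trael_genome or a bare DNAStringSet everywhere downstream.
as_genome_seq <- function(genome) {
  if (inherits(genome, "trael_genome")) genome$seq
  else if (methods::is(genome, "DNAStringSet")) genome
  else stop("genome must be a trael_genome or DNAStringSet")
}

genome_lengths <- function(genome) {
  if (inherits(genome, "trael_genome")) genome$chrom_lengths
  else setNames(Biostrings::width(genome), names(genome))
}

#' Mask reference intervals with Ns
#'
#' Replaces every base inside the given intervals with N, leaving sequence
#' length unchanged. Used to neutralise multi-copy stretches (e.g. a tandem
#' gene array and an integrated promoter cassette) before alignment so that
#' reads from integrated copies cannot generate multi-mapping artefacts.
#'
#' @param genome `trael_genome` or `DNAStringSet`.
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open). `closed_1based = TRUE` interprets them instead as
#'   1-based closed coordinates as printed in genome-browser style notation.
#' @param closed_1based logical; see above.
#' @return same class as `genome`, with masked sequence.
#' @export
mask_reference <- function(genome, intervals, closed_1based = FALSE) {
  seqs <- as_genome_seq(genome)
  lens <- genome_lengths(genome)
  if (is.null(intervals) || nrow(intervals) == 0L) return(genome)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  start1 <- if (closed_1based) intervals$start else intervals$start + 1L
  end1 <- intervals$end
  if (!all(intervals$chrom %in% names(seqs)))
    stop("mask interval on unknown chromosome")
  if (any(start1 < 1L) || any(end1 > lens[intervals$chrom]) || any(start1 > end1))
    stop("mask interval outside chromosome bounds")
  for (ch in unique(intervals$chrom)) {
    sel <- intervals$chrom == ch
    at <- IRanges::IRanges(start1[sel], end1[sel])
    if (!isTRUE(all(IRanges::width(IRanges::reduce(at)) ==
                    IRanges::width(at))) && length(at) > 1L) {
      at <- IRanges::reduce(at)
    }
    seqs[[ch]] <- Biostrings::replaceAt(seqs[[ch]], at,
                                        strrep("N", IRanges::width(at)))
  }
  if (inherits(genome, "trael_genome")) {
    genome$seq <- seqs
    genome
  } else {
    seqs
  }
}

#' Write a genome to FASTA
#'
#' @param genome `trael_genome` or `DNAStringSet`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome_seq(genome), path)
  invisible(path)
}
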