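#' Extract the inline UMI from raw reads
#'
#' Removes the first `umi_length` bases of each read, stores them as the UMI
#' and appends them to the read identifier with a fixed delimiter so that the
#' UMI survives a SAM round-trip. Qualities are trimmed in register. Reads
#' shorter than `umi_length + 1` cannot carry any genomic sequence and are
#' rejected (counted in the `rejected` attribute).
#'
#' @param reads data.frame with `read_id`, `sequence`, `qualities`.
#' @param umi_length UMI length (8 for this library design).
#' @param delim delimiter between original read id and UMI.
#' @return data.frame with `read_id` (UMI-suffixed), `umi`, `sequence`,
#'   `qualities`; attribute `rejected` holds the number of dropped reads.
#' @export
extract_umi <- function(reads, umi_length = 8L, delim = ":") {
  len <- nchar(reads$sequence)
  ok <- len >= umi_length + 1L
  out <- reads[ok, , drop = FALSE]
  umi <- substr(out$sequence, 1L, umi_length)
  out <- data.frame(read_id = paste0(out$read_id, delim, umi),
                    umi = umi,
                    sequence = substr(out$sequence, umi_length + 1L,
                                      nchar(out$sequence)),
                    qualities = substr(out$qualities, umi_length + 1L,
                                       nchar(out$qualities)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejected") <- sum(!ok)
  out
}

#' Trim the poly-T spacer after UMI removal
#'
#' Removes leading T bases, at most `max_t`, stopping at the first non-T, and
#' records how many were removed per read.
#'
#' @param reads data.frame as returned by [extract_umi()].
#' @param max_t maximum number of Ts to remove (3 for this library design).
#' @return input data.frame with trimmed `sequence`/`qualities` and an added
#'   `polyT_removed` column.
#' @export
trim_polyT <- function(reads, max_t = 3L) {
  m <- regexpr(sprintf("^T{1,%d}", max_t), reads$sequence)
  k <- ifelse(m == 1L, attr(m, "match.length"), 0L)
  reads$sequence <- substr(reads$sequence, k + 1L, nchar(reads$sequence))
  reads$qualities <- substr(reads$qualities, k + 1L, nchar(reads$qualities))
  reads$polyT_removed <- as.integer(k)
  reads
}

#' Sequence-based deduplication on the 5' prefix
#'
#' Keeps the first occurrence of each distinct `prefix_length`-base 5' prefix
#' (by default 23 bp: the 8 bp UMI plus the first 15 bp of genomic sequence),
#' preserving order otherwise. Applied to raw reads *before* UMI extraction,
#' this removes PCR copies of molecules from multi-copy loci that would
#' otherwise survive alignment-based UMI deduplication by mapping to different
#' repeat copies at random. Reads shorter than the prefix cannot be collided
#' safely and are kept, flagged in the `short_prefix` column.
#'
#' @param reads data.frame with `read_id`, `sequence` (raw, UMI still
#'   attached).
#' @param prefix_length prefix length in bp.
#' @return deduplicated data.frame (order preserved) with a `short_prefix`
#'   flag column; attribute `discarded` counts removed reads.
#' @export
dedup_by_sequence <- function(reads, prefix_length = 23L) {
  key <- substr(reads$sequence, 1L, prefix_length)
  short <- nchar(reads$sequence) < prefix_length
  keep <- !duplicated(key) | short
  out <- reads[keep, , drop = FALSE]
  out$short_prefix <- short[keep]
  rownames(out) <- NULL
  attr(out, "discarded") <- sum(!keep)
  out
}
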