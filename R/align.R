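#' Exact-match alignment of pre-processed reads
#'
#' Minimal aligner sufficient for simulator-generated reads: each read's first
#' `seed_length` bases are matched exactly against both strands of the
#' reference (via [Biostrings::matchPDict()]) and candidate placements are
#' verified over the full read length. Reads with exactly one verified
#' placement are reported; reads with several are discarded as multi-mapping
#' (counted, with the number of candidate placements recorded); reads with
#' none, or shorter than the seed, are counted as unmapped. Because matching
#' is exact, a reference masked with Ns can never attract alignments inside
#' the masked intervals.
#'
#' Records carry the full genomic span as 0-based half-open `start`/`end` and
#' the strand; the 5'-most base of the read (the break-adjacent nucleotide)
#' is `start` for forward and `end - 1` for reverse alignments.
#'
#' @param reads data.frame with `read_id`, `sequence` and (optionally) `umi`
#'   columns, as produced by [extract_umi()] + [trim_polyT()].
#' @param genome `trael_genome` or `DNAStringSet`.
#' @param seed_length exact-match seed length in bp.
#' @param umi_delim delimiter used to recover the UMI from `read_id` when no
#'   `umi` column is present.
#' @return data.frame with `read_id`, `umi`, `chrom`, `start`, `end`,
#'   `strand`, `mapq`; attributes `counters` (named vector: mapped, unmapped,
#'   multimapped, too_short) and `multimap` (data.frame `read_id`,
#'   `n_placements` for discarded multi-mappers).
#' @export
align_reads <- function(reads, genome, seed_length = 20L, umi_delim = ":") {
  seqs <- as_genome_seq(genome)
  if (!nrow(reads)) stop("no reads to align")
  umi <- reads$umi
  if (is.null(umi)) umi <- sub(sprintf(".*%s", umi_delim), "", reads$read_id)

  len <- nchar(reads$sequence)
  pre <- substr(reads$sequence, 1L, seed_length)
  eligible <- len >= seed_length & !grepl("[^ACGT]", pre)
  idx <- which(eligible)
  empty <- data.frame(read_id = character(), umi = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), mapq = integer())
  if (!length(idx)) {
    attr(empty, "counters") <- c(mapped = 0L, unmapped = 0L, multimapped = 0L,
                                 too_short = sum(!eligible))
    attr(empty, "multimap") <- data.frame(read_id = character(),
                                          n_placements = integer())
    return(empty)
  }

  pset <- Biostrings::DNAStringSet(pre[idx])
  pd_fw <- Biostrings::PDict(pset)
  pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(pset))
  rc_full <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(reads$sequence[idx])))

  cand <- vector("list", 2L * length(seqs))
  for (ci in seq_along(seqs)) {
    subj <- seqs[[ci]]
    chrstr <- as.character(subj)
    L <- nchar(chrstr)
    ch <- names(seqs)[ci]

    hits <- Biostrings::matchPDict(pd_fw, subj)
    st <- Biostrings::startIndex(hits)
    nh <- lengths(st)
    if (any(nh > 0L)) {
      ri <- rep(seq_along(idx)[nh > 0L], nh[nh > 0L])
      s1 <- unlist(st[nh > 0L])                  # 1-based start of seed
      rl <- len[idx][ri]
      ok <- s1 + rl - 1L <= L &
        substring(chrstr, s1, s1 + rl - 1L) == reads$sequence[idx][ri]
      cand[[2L * ci - 1L]] <- data.frame(
        r = idx[ri[ok]], chrom = ch, start = s1[ok] - 1L,
        end = s1[ok] - 1L + rl[ok], strand = "+")
    }

    hits <- Biostrings::matchPDict(pd_rc, subj)
    st <- Biostrings::startIndex(hits)
    nh <- lengths(st)
    if (any(nh > 0L)) {
      ri <- rep(seq_along(idx)[nh > 0L], nh[nh > 0L])
      s1 <- unlist(st[nh > 0L])
      rl <- len[idx][ri]
      end1 <- s1 + seed_length - 1L              # 1-based rightmost seed base
      start1 <- end1 - rl + 1L
      ok <- start1 >= 1L &
        substring(chrstr, start1, end1) == rc_full[ri]
      cand[[2L * ci]] <- data.frame(
        r = idx[ri[ok]], chrom = ch, start = start1[ok] - 1L,
        end = end1[ok], strand = "-")
    }
  }
  cand <- do.call(rbind, cand[!vapply(cand, is.null, TRUE)])

  too_short <- sum(!eligible)
  if (is.null(cand) || !nrow(cand)) {
    attr(empty, "counters") <- c(mapped = 0L, unmapped = length(idx),
                                 multimapped = 0L, too_short = too_short)
    attr(empty, "multimap") <- data.frame(read_id = character(),
                                          n_placements = integer())
    return(empty)
  }
  nplace <- table(cand$r)
  uniq <- as.integer(names(nplace)[nplace == 1L])
  multi <- as.integer(names(nplace)[nplace > 1L])
  out <- cand[cand$r %in% uniq, , drop = FALSE]
  out <- data.frame(read_id = reads$read_id[out$r], umi = umi[out$r],
                    chrom = out$chrom, start = out$start, end = out$end,
                    strand = out$strand, mapq = rep(42L, nrow(out)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand, out$read_id), ]
  rownames(out) <- NULL
  attr(out, "counters") <- c(
    mapped = nrow(out),
    unmapped = length(idx) - length(uniq) - length(multi),
    multimapped = length(multi),
    too_short = too_short)
  attr(out, "multimap") <- data.frame(
    read_id = reads$read_id[multi],
    n_placements = as.integer(nplace[as.character(multi)]))
  out
}

cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MDN=X]", cigar)), function(ops) {
    if (!length(ops)) return(NA_integer_)
    sum(as.integer(sub("[MDN=X]", "", ops)))
  }, integer(1))
}

#' Import alignments from a SAM/BAM file
#'
#' Reads mapped records from any aligner's output into the same record shape
#' produced by [align_reads()], converting 1-based SAM coordinates to 0-based
#' half-open spans (reference width from the CIGAR). UMIs are recovered from
#' UMI-suffixed read names.
#'
#' @param path SAM or BAM file.
#' @param genome optional `trael_genome`/`DNAStringSet`; when given, contig
#'   names are checked against the reference (error on empty intersection).
#' @param umi_delim delimiter separating the UMI suffix in read names.
#' @return data.frame as in [align_reads()]; attribute `counters` holds
#'   mapped/unmapped record counts.
#' @export
import_sam <- function(path, genome = NULL, umi_delim = ":") {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mapq")))[[1]]
  mapped <- !bitwAnd(b$flag, 4L)
  if (!is.null(genome)) {
    if (!length(intersect(levels(b$rname), names(as_genome_seq(genome)))))
      stop("no contig names shared between SAM and reference")
  }
  rw <- cigar_ref_width(b$cigar[mapped])
  out <- data.frame(
    read_id = b$qname[mapped],
    umi = sub(sprintf(".*%s", umi_delim), "", b$qname[mapped]),
    chrom = as.character(b$rname[mapped]),
    start = b$pos[mapped] - 1L,
    end = b$pos[mapped] - 1L + rw,
    strand = ifelse(bitwAnd(b$flag[mapped], 16L) > 0L, "-", "+"),
    mapq = b$mapq[mapped],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counters") <- c(mapped = sum(mapped), unmapped = sum(!mapped))
  out
}

#' Write alignment records as SAM
#'
#' Minimal SAM writer (header plus one `<width>M` record per alignment; no
#' stored sequence) so that alignments round-trip through standard tools.
#'
#' @param aln alignment data.frame from [align_reads()] or [umi_dedup()].
#' @param genome `trael_genome` or `DNAStringSet` (for `@SQ` header lines).
#' @param path output path.
#' @export
write_sam <- function(aln, genome, path) {
  lens <- genome_lengths(genome)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                 aln$read_id, ifelse(aln$strand == "-", 16L, 0L), aln$chrom,
                 aln$start + 1L, aln$mapq, aln$end - aln$start)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
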