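#' UMI-aware deduplication of alignments
#'
#' Collapses alignment records to unique molecules using the key
#' (chromosome, 5' mapping position, orientation, UMI): the 5' position is
#' the leftmost mapped base for forward records and the rightmost for reverse
#' records. Records are first put into a deterministic sort order
#' (chromosome, position, strand, UMI, read id) and the first record of each
#' key is retained, so the operation is idempotent and order-insensitive.
#' Records without a parseable UMI are rejected and counted.
#'
#' @param aln alignment data.frame ([align_reads()] / [import_sam()]).
#' @param umi_length expected UMI length.
#' @return deduplicated alignment data.frame; attributes `n_duplicates` and
#'   `n_rejected`.
#' @export
umi_dedup <- function(aln, umi_length = 8L) {
  ok <- !is.na(aln$umi) & grepl(sprintf("^[ACGTN]{%d}$", umi_length), aln$umi)
  x <- aln[ok, , drop = FALSE]
  pos5 <- ifelse(x$strand == "+", x$start, x$end - 1L)
  o <- order(x$chrom, pos5, x$strand, x$umi, x$read_id)
  x <- x[o, , drop = FALSE]
  key <- paste(x$chrom, pos5[o], x$strand, x$umi, sep = "\r")
  keep <- !duplicated(key)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- sum(!keep)
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Truncate alignments to single-nucleotide break sites
#'
#' Each record is reduced to the 1 nt at its 5' end in read orientation: the
#' leftmost mapped coordinate for forward records, the rightmost for reverse
#' records. This base is the last nucleotide 5' of the strand break captured
#' by the library chemistry.
#'
#' @param aln alignment data.frame.
#' @return data.frame with `chrom`, `position`, `strand`, `umi`.
#' @export
truncate_to_break <- function(aln) {
  data.frame(chrom = aln$chrom,
             position = ifelse(aln$strand == "+", aln$start, aln$end - 1L),
             strand = aln$strand,
             umi = if (is.null(aln$umi)) NA_character_ else aln$umi,
             stringsAsFactors = FALSE)
}

#' Count break sites in running windows, by strand
#'
#' Sums sites in running windows of `window_size` bp spaced every `step` bp
#' along each chromosome (a site contributes to every window containing it;
#' containment is half-open on the single break coordinate). Columns `fwd`
#' and `rev` hold the forward (F) and reverse (R) strand counts entering the
#' read-polarity statistic.
#'
#' @param sites break-site data.frame ([truncate_to_break()] or simulator
#'   output).
#' @param genome `trael_genome`, `DNAStringSet`, or named vector of
#'   chromosome lengths.
#' @param window_size window width in bp.
#' @param step spacing between window starts in bp; `step <= window_size`.
#' @return `window_track`: data.frame `chrom`, `start`, `end`, `fwd`, `rev`,
#'   `included` with attributes `window_size`, `step`, `norm` (`"raw"`) and
#'   `chrom_lengths`.
#' @export
count_windows <- function(sites, genome, window_size = 50L, step = 10L) {
  stopifnot(window_size >= step, step >= 1L)
  lens <- if (is.numeric(genome)) genome else genome_lengths(genome)
  if (is.null(names(lens))) stop("chromosome lengths must be named")
  tracks <- lapply(names(lens), function(ch) {
    L <- lens[[ch]]
    starts <- seq.int(0L, max(0L, L - 1L), by = step)
    nw <- length(starts)
    s <- sites[sites$chrom == ch, , drop = FALSE]
    cnt <- function(p) {
      if (!length(p)) return(integer(nw))
      lo <- pmax(0L, ceiling((p - window_size + 1L) / step))
      hi <- pmin(nw - 1L, floor(p / step))
      n <- hi - lo + 1L
      ok <- n > 0L
      widx <- rep(lo[ok], n[ok]) + sequence(n[ok]) - 1L
      tabulate(widx + 1L, nbins = nw)
    }
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, L),
               fwd = cnt(s$position[s$strand == "+"]),
               rev = cnt(s$position[s$strand == "-"]),
               included = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tracks)
  rownames(out) <- NULL
  structure(out, window_size = window_size, step = step, norm = "raw",
            chrom_lengths = lens,
            class = c("window_track", "data.frame"))
}

track_attrs <- function(track) {
  list(window_size = attr(track, "window_size"), step = attr(track, "step"),
       norm = attr(track, "norm"), chrom_lengths = attr(track, "chrom_lengths"))
}

restore_track <- function(df, at, norm = at$norm) {
  structure(df, window_size = at$window_size, step = at$step, norm = norm,
            chrom_lengths = at$chrom_lengths,
            class = c("window_track", "data.frame"))
}

#' Exclude blacklisted windows from a track
#'
#' Marks every window overlapping any interval by >= 1 bp as excluded;
#' excluded windows carry no counts into totals, normalisation factors or
#' downstream statistics. Typical blacklists cover non-single-copy regions
#' (rDNA, mitochondrial DNA, 2-micron plasmid, sub-telomeres, transposons and
#' their LTRs).
#'
#' @param track `window_track`.
#' @param intervals data.frame `chrom`, `start`, `end` (0-based half-open),
#'   e.g. from [read_bed()].
#' @return track with updated `included` flags.
#' @export
filter_blacklist <- function(track, intervals) {
  if (is.null(intervals) || !nrow(intervals)) return(track)
  at <- track_attrs(track)
  excl <- logical(nrow(track))
  for (ch in unique(intervals$chrom)) {
    sel <- which(track$chrom == ch)
    if (!length(sel)) next
    win <- IRanges::IRanges(track$start[sel] + 1L, track$end[sel])
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    bl <- IRanges::IRanges(iv$start + 1L, iv$end)
    excl[sel] <- IRanges::overlapsAny(win, bl)
  }
  track$included <- track$included & !excl
  restore_track(track, at)
}

#' Reads-per-million normalisation
#'
#' Scales the counts of every included window by `1e6 / total`, where `total`
#' is the sum of forward + reverse counts over included windows. Excluded
#' windows neither contribute to the factor nor are rescaled.
#'
#' @param track raw `window_track`.
#' @return track in `"rpm"` normalisation state.
#' @export
normalize_rpm <- function(track) {
  at <- track_attrs(track)
  if (at$norm != "raw") stop("track already normalized (state: ", at$norm, ")")
  inc <- track$included
  total <- sum(track$fwd[inc]) + sum(track$rev[inc])
  if (total == 0) stop("zero total counts in included windows")
  f <- 1e6 / total
  track$fwd[inc] <- track$fwd[inc] * f
  track$rev[inc] <- track$rev[inc] * f
  restore_track(track, at, norm = "rpm")
}

#' Trimmed-mean enrichment normalisation across libraries
#'
#' Matches the read-count distributions of several RPM tracks sharing one
#' window grid: for each track the mean of included per-window totals lying
#' between its `lo_pct` and `hi_pct` percentiles is computed, and each track
#' is rescaled so these trimmed means equal their cross-track geometric mean.
#' The operation is scale-only, so per-window polarity values are unchanged.
#'
#' @param tracks list of >= 2 `window_track`s in `"rpm"` state on identical
#'   grids.
#' @param lo_pct,hi_pct percentile band (defaults 20 and 90).
#' @return list of tracks in `"rpm+enrichment"` state; each carries its scale
#'   factor in attribute `enrichment_factor`.
#' @export
normalize_enrichment <- function(tracks, lo_pct = 20, hi_pct = 90) {
  stopifnot(is.list(tracks), length(tracks) >= 2L)
  ats <- lapply(tracks, track_attrs)
  if (any(vapply(ats, function(a) a$norm, "") != "rpm"))
    stop("all tracks must be in rpm state")
  g <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (!identical(t$chrom, g$chrom) || !identical(t$start, g$start))
      stop("tracks must share an identical window grid")
  }
  tmeans <- vapply(tracks, function(t) {
    tot <- t$fwd[t$included] + t$rev[t$included]
    q <- quantile(tot, c(lo_pct, hi_pct) / 100, names = FALSE)
    band <- tot >= q[1L] & tot <= q[2L]
    if (sum(band) < 10L)
      stop("fewer than 10 windows inside the percentile band")
    mean(tot[band])
  }, numeric(1))
  target <- exp(mean(log(tmeans)))
  Map(function(t, tm, at) {
    f <- target / tm
    t$fwd[t$included] <- t$fwd[t$included] * f
    t$rev[t$included] <- t$rev[t$included] * f
    out <- restore_track(t, at, norm = "rpm+enrichment")
    attr(out, "enrichment_factor") <- f
    out
  }, tracks, tmeans, ats)
}
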