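#' Compute the read-polarity profile of a window track
#'
#' Per included window, polarity = (R - F)/(R + F) where F and R are the
#' forward and reverse counts. Positive values indicate predominantly
#' left-to-right replication (excess reverse reads), negative values
#' right-to-left. Windows with F + R = 0, and excluded windows, are undefined
#' (NA). Polarity is invariant under any positive rescaling of both strands,
#' so raw, RPM and enrichment-normalised tracks give identical profiles.
#'
#' @param track `window_track` in any normalisation state.
#' @return `polarity_profile`: the track with an added `polarity` column.
#' @export
compute_polarity <- function(track) {
  at <- track_attrs(track)
  tot <- track$fwd + track$rev
  track$polarity <- ifelse(track$included & tot > 0,
                           (track$rev - track$fwd) / tot, NA_real_)
  out <- restore_track(track, at)
  class(out) <- c("polarity_profile", class(out))
  out
}

# Flank-mean transition scores. For each window, the mean defined polarity
# over the `flank` windows on each side (undefined windows skipped, not
# zero-filled) and the mean coverage over included flank windows.
transition_scores <- function(profile, flank) {
  res <- lapply(split(seq_len(nrow(profile)), profile$chrom), function(sel) {
    pol <- profile$polarity[sel]
    cov <- ifelse(profile$included[sel], profile$fwd[sel] + profile$rev[sel],
                  NA_real_)
    n <- length(sel)
    lm <- rm <- cv <- rep(NA_real_, n)
    if (n < 2L * flank + 1L) {
      return(data.frame(row = sel, left_mean = lm, right_mean = rm,
                        coverage = cv))
    }
    def <- !is.na(pol)
    S <- cumsum(ifelse(def, pol, 0))
    C <- cumsum(def)
    Sc <- cumsum(ifelse(is.na(cov), 0, cov))
    Cc <- cumsum(!is.na(cov))
    i <- (flank + 1L):(n - flank)
    pad <- function(x) c(rep(0, flank + 1L), x)[i]  # = x[i - flank - 1]
    nl <- C[i - 1L] - pad(C)                        # defined count, left flank
    sl <- S[i - 1L] - pad(S)
    nr <- C[i + flank] - C[i]
    sr <- S[i + flank] - S[i]
    lm[i] <- ifelse(nl > 0, sl / nl, NA_real_)
    rm[i] <- ifelse(nr > 0, sr / nr, NA_real_)
    ncv <- (Cc[i + flank] - Cc[i]) + (Cc[i - 1L] - pad(Cc))
    scv <- (Sc[i + flank] - Sc[i]) + (Sc[i - 1L] - pad(Sc))
    cv[i] <- ifelse(ncv > 0, scv / ncv, NA_real_)
    data.frame(row = sel, left_mean = lm, right_mean = rm, coverage = cv)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$row), ]
  out$score <- out$right_mean - out$left_mean
  out
}

# merge candidate window indices lying within `gap` of each other; keep the
# maximum-score representative (ties: leftmost)
merge_candidates <- function(idx, score, gap) {
  if (!length(idx)) return(integer())
  grp <- cumsum(c(1L, diff(idx) > gap))
  vapply(split(seq_along(idx), grp), function(g) {
    g[which.max(score[g])]
  }, integer(1))
}

#' Call replication origins from polarity transitions
#'
#' Scores every window as mean(polarity over the right flank) - mean(left
#' flank); a sharp negative-to-positive transition (left mean < 0 < right
#' mean, score above threshold, adequate flank coverage) marks an active
#' replication origin. Candidates within one flank width of each other are
#' merged, reporting the maximum-score window. Output is deterministic.
#'
#' @param profile `polarity_profile` from [compute_polarity()].
#' @param flank number of windows per flank (>= 3).
#' @param min_score minimum transition score (right mean - left mean; the
#'   score lies in \[-2, 2\]).
#' @param min_coverage minimum mean F+R coverage over the flanks, in the
#'   track's count units.
#' @return data.frame of calls sorted by position: `chrom`, `position`
#'   (center of the transition window), `score`, `left_mean`, `right_mean`,
#'   `coverage`.
#' @export
call_origins <- function(profile, flank = 15L, min_score = 0.5,
                         min_coverage = 5) {
  stopifnot(flank >= 3L)
  at <- track_attrs(profile)
  ts <- transition_scores(profile, flank)
  if (all(is.na(ts$score))) {
    nw <- table(profile$chrom)
    if (any(nw < 2L * flank + 1L))
      warning("flank exceeds chromosome extent for some chromosome(s)")
  }
  cand <- which(!is.na(ts$score) & ts$score >= min_score &
                ts$left_mean < 0 & ts$right_mean > 0 &
                !is.na(ts$coverage) & ts$coverage >= min_coverage)
  out <- lapply(split(cand, profile$chrom[cand]), function(ci) {
    keep <- merge_candidates(ci, ts$score[ci], flank)
    ci[keep]
  })
  rows <- sort(unlist(out, use.names = FALSE))
  data.frame(chrom = profile$chrom[rows],
             position = profile$start[rows] + at$window_size %/% 2L,
             score = ts$score[rows],
             left_mean = ts$left_mean[rows],
             right_mean = ts$right_mean[rows],
             coverage = ts$coverage[rows],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call fork-convergence zones from polarity transitions
#'
#' Symmetric counterpart of [call_origins()] for gradual positive-to-negative
#' transitions, which occur where forks from neighbouring origins meet.
#' Because convergence positions vary from cell to cell, a zone is reported
#' as an interval spanning contiguous windows whose transition score is below
#' `-min_score` (runs separated by at most one flank width are merged), with
#' `position` at the window of most negative score.
#'
#' @inheritParams call_origins
#' @return data.frame of zones: `chrom`, `start`, `end` (0-based half-open),
#'   `position` (score minimum), `score` (most negative flank-difference).
#' @export
call_convergence <- function(profile, flank = 15L, min_score = 0.5,
                             min_coverage = 5) {
  stopifnot(flank >= 3L)
  at <- track_attrs(profile)
  ts <- transition_scores(profile, flank)
  cand <- which(!is.na(ts$score) & ts$score <= -min_score &
                ts$left_mean > 0 & ts$right_mean < 0 &
                !is.na(ts$coverage) & ts$coverage >= min_coverage)
  zones <- lapply(split(cand, profile$chrom[cand]), function(ci) {
    if (!length(ci)) return(NULL)
    grp <- cumsum(c(1L, diff(ci) > flank))
    do.call(rbind, lapply(split(ci, grp), function(g) {
      best <- g[which.min(ts$score[g])]
      data.frame(chrom = profile$chrom[g[1L]],
                 start = profile$start[g[1L]],
                 end = profile$end[g[length(g)]],
                 position = profile$start[best] + at$window_size %/% 2L,
                 score = ts$score[best])
    }))
  })
  out <- do.call(rbind, zones[!vapply(zones, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), position = integer(), score = numeric())
  }
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Average replicate tracks for display profiles
#'
#' Mean of normalised replicate tracks (same grid), the standard display
#' profile for biological replicates before computing polarity.
#'
#' @param tracks list of `window_track`s on one grid and normalisation state.
#' @return single averaged `window_track`.
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  at <- track_attrs(tracks[[1L]])
  g <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (!identical(t$start, g$start) || !identical(t$chrom, g$chrom))
      stop("tracks must share an identical window grid")
    g$fwd <- g$fwd + t$fwd
    g$rev <- g$rev + t$rev
    g$included <- g$included & t$included
  }
  g$fwd <- g$fwd / length(tracks)
  g$rev <- g$rev / length(tracks)
  restore_track(g, at)
}
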