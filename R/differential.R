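# Exact conditional negative-binomial two-sample count test.
#
# Group sums sA, sB are modelled as NB with means proportional to the summed
# library sizes SA, SB and common per-replicate dispersion alpha (variance
# mu + alpha*mu^2); the test conditions on the total t = sA + sB. With
# alpha = 0 this reduces to the exact conditional binomial (Poisson) test.
# `lfc = 0` gives a two-sided minimum-likelihood p-value for H0: equal rates;
# `lfc > 0` tests the composite null |log2 fold change| <= lfc by summing the
# two tail probabilities computed at the respective fold-change boundaries.
cond_nb_test <- function(sB, t, SA, SB, nA, nB, alpha, lfc = 0) {
  if (t == 0L) return(NA_real_)
  conditional_probs <- function(rho) {   # rho = rate ratio B/A
    muB <- rho * SB / (SA + rho * SB) * t
    muA <- t - muB
    k <- 0:t
    if (alpha <= 0) {
      lp <- dbinom(k, t, muB / t, log = TRUE)
    } else {
      lp <- dnbinom(k, size = nB / alpha, mu = muB, log = TRUE) +
        dnbinom(t - k, size = nA / alpha, mu = muA, log = TRUE)
      lp <- lp - max(lp)
    }
    p <- exp(lp)
    p / sum(p)
  }
  if (lfc == 0) {
    # two-sided minimum-likelihood mid-p: discrete exact tests are otherwise
    # conservative; the mid-p correction restores near-nominal size
    p <- conditional_probs(1)
    obs <- p[sB + 1L]
    lower <- p < obs * (1 - 1e-7)
    at <- abs(p - obs) <= obs * 1e-7
    sum(p[lower]) + 0.5 * sum(p[at])
  } else {
    # composite null |log2FC| <= lfc: one-sided tail under each worst-case
    # boundary, doubled (each tail p is valid over the whole composite null)
    pu <- conditional_probs(2^lfc)       # boundary: B truly lfc-fold up
    pd <- conditional_probs(2^(-lfc))
    min(1, 2 * min(sum(pu[(sB + 1L):(t + 1L)]), sum(pd[1L:(sB + 1L)])))
  }
}

# Pooled method-of-moments common dispersion across windows.
estimate_common_dispersion <- function(counts, groups, libsize, min_mean = 1) {
  gm <- exp(mean(log(libsize)))
  y <- sweep(counts, 2L, gm / libsize, `*`)
  num <- den <- keep <- numeric(nrow(counts))
  for (g in unique(groups)) {
    j <- which(groups == g)
    m <- rowMeans(y[, j, drop = FALSE])
    v <- apply(y[, j, drop = FALSE], 1L, var)
    num <- num + (length(j) - 1L) * (v - m)
    den <- den + (length(j) - 1L) * m^2
  }
  mtot <- rowMeans(y)
  ok <- den > 0 & mtot >= min_mean
  if (!any(ok)) return(0)
  max(0, median(num[ok] / den[ok]))
}

#' Windowed differential count test between two conditions
#'
#' Tests, per running window, whether single-strand read counts differ
#' between two conditions with replicates, targeting localized fork
#' accumulation (stalling). Raw (unnormalised) counts are used with
#' library-size offsets; an exact conditional negative-binomial test with a
#' single method-of-moments common dispersion shared across windows provides
#' the p-values, which are Benjamini-Hochberg adjusted across tested windows.
#' Setting `lfc > 0` tests the composite null hypothesis that the fold change
#' is at most `2^lfc`, so that only biologically substantial differences can
#' reach significance.
#'
#' @param condA_tracks,condB_tracks lists of >= 2 replicate `window_track`s
#'   per condition, raw counts, identical grids. Alternatively lists of
#'   break-site data.frames, which are counted at `window`/`step` (then
#'   `genome` is required).
#' @param window,step window size and spacing in bp used when counting site
#'   lists (defaults 200 and 50).
#' @param strand which strand's counts to test (`"forward"` or `"reverse"`).
#' @param genome genome/lengths, only needed when site lists are supplied.
#' @param lfc log2 fold-change threshold of the composite null (0 = plain
#'   equal-rate test).
#' @param dispersion optional fixed common dispersion; estimated when NULL.
#' @param fdr_threshold FDR level defining the `significant` flag.
#' @return data.frame per tested window (windows with zero total count are
#'   dropped): `chrom`, `start`, `end`, `countA`, `countB` (summed raw
#'   counts), `log2FC` (library-size adjusted), `pvalue`, `fdr`,
#'   `significant`; attribute `dispersion` holds the common dispersion used.
#' @export
differential_windows <- function(condA_tracks, condB_tracks, window = 200L,
                                 step = 50L, strand = c("forward", "reverse"),
                                 genome = NULL, lfc = 0, dispersion = NULL,
                                 fdr_threshold = 0.05) {
  strand <- match.arg(strand)
  as_tracks <- function(x) {
    lapply(x, function(el) {
      if (inherits(el, "window_track")) {
        if (attr(el, "norm") != "raw")
          stop("differential testing requires raw (unnormalised) counts")
        el
      } else {
        if (is.null(genome))
          stop("genome required when supplying break-site lists")
        count_windows(el, genome, window_size = window, step = step)
      }
    })
  }
  A <- as_tracks(condA_tracks)
  B <- as_tracks(condB_tracks)
  if (length(A) < 2L || length(B) < 2L)
    stop("each condition needs >= 2 replicates; for single replicates use ",
         "descriptive fold changes (screen_fold_change) instead")
  g <- A[[1L]]
  for (t in c(A[-1L], B)) {
    if (!identical(t$chrom, g$chrom) || !identical(t$start, g$start))
      stop("replicate tracks must share an identical window grid")
  }
  col <- if (strand == "forward") "fwd" else "rev"
  inc <- Reduce(`&`, lapply(c(A, B), function(t) t$included))
  counts <- vapply(c(A, B), function(t) t[[col]][inc], numeric(sum(inc)))
  groups <- rep(c("A", "B"), c(length(A), length(B)))
  libsize <- colSums(counts)
  if (all(counts == 0)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      countA = numeric(), countB = numeric(),
                      log2FC = numeric(), pvalue = numeric(), fdr = numeric(),
                      significant = logical())
    attr(out, "dispersion") <- 0
    return(out)
  }
  alpha <- if (is.null(dispersion)) {
    estimate_common_dispersion(counts, groups, libsize)
  } else dispersion

  sA <- rowSums(counts[, groups == "A", drop = FALSE])
  sB <- rowSums(counts[, groups == "B", drop = FALSE])
  SA <- sum(libsize[groups == "A"])
  SB <- sum(libsize[groups == "B"])
  tt <- sA + sB
  tested <- which(tt > 0)
  pv <- vapply(tested, function(i) {
    cond_nb_test(sB[i], tt[i], SA, SB, sum(groups == "A"), sum(groups == "B"),
                 alpha, lfc)
  }, numeric(1))
  out <- data.frame(chrom = g$chrom[inc][tested],
                    start = g$start[inc][tested],
                    end = g$end[inc][tested],
                    countA = sA[tested], countB = sB[tested],
                    log2FC = log2(((sB[tested] + 0.5) / (SB + 1)) /
                                  ((sA[tested] + 0.5) / (SA + 1))),
                    pvalue = pv, stringsAsFactors = FALSE)
  out$fdr <- p.adjust(out$pvalue, method = "BH")
  out$significant <- out$fdr < fdr_threshold
  rownames(out) <- NULL
  attr(out, "dispersion") <- alpha
  out
}
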