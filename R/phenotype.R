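#' Percentage of copy-number-variant alleles in a gel lane
#'
#' CNV percent = 100 * (intensity of all CNV bands) / (intensity of CNV and
#' parental bands), computed from band densitometry values for one lane.
#' Band class assignment (parental vs CNV) is supplied with the input; the
#' result is invariant under uniform rescaling of all lane intensities.
#'
#' @param intensity numeric vector of band intensities (>= 0).
#' @param class character vector, one of `"parental"` or `"cnv"` per band.
#' @return CNV percentage in \[0, 100\].
#' @export
cnv_percent <- function(intensity, class) {
  stopifnot(length(intensity) == length(class), length(intensity) >= 1L)
  if (!all(class %in% c("parental", "cnv")))
    stop("band class must be 'parental' or 'cnv'")
  if (!any(class == "parental")) stop("lane needs at least one parental band")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("band intensities must be finite and >= 0")
  total <- sum(intensity)
  if (total <= 0) stop("zero total band intensity")
  100 * sum(intensity[class == "cnv"]) / total
}

#' Per-lane CNV percentages from a band table
#'
#' @param band_table data.frame with columns `sample`, `band`, `intensity`,
#'   `class` and optionally `condition`; one row per band
#'   (see [read_band_table()]).
#' @return data.frame with one row per lane: `sample`, `condition` (if
#'   present), `cnv_percent`.
#' @export
cnv_table <- function(band_table) {
  stopifnot(all(c("sample", "intensity", "class") %in% names(band_table)))
  lanes <- split(band_table, band_table$sample)
  out <- do.call(rbind, lapply(lanes, function(l) {
    data.frame(sample = l$sample[1L],
               condition = if (is.null(l$condition)) NA_character_
                           else l$condition[1L],
               cnv_percent = cnv_percent(l$intensity, l$class))
  }))
  rownames(out) <- NULL
  out
}

#' Read a band-intensity table from TSV
#'
#' Expected columns: `sample`, `condition`, `band`, `intensity`, `class`
#' (`parental`/`cnv`).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_band_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "band", "intensity", "class") %in% names(x)))
  x
}

#' Fold change in CNV between mutant and wild type
#'
#' Fold change = mutant CNV percent / wild-type CNV percent, with the screen
#' classification bands: enhancer if the fold change exceeds
#' `enhancer_threshold` (default 2), suppressor if below
#' `suppressor_threshold` (default 0.5), otherwise neither.
#'
#' @param mutant_pct,wildtype_pct CNV percentages (wild type > 0).
#' @param enhancer_threshold,suppressor_threshold classification cut-offs.
#' @return data.frame `fold_change`, `class`.
#' @export
screen_fold_change <- function(mutant_pct, wildtype_pct,
                               enhancer_threshold = 2,
                               suppressor_threshold = 0.5) {
  if (any(wildtype_pct <= 0))
    stop("wild-type CNV percentage must be > 0 (fold change undefined)")
  fc <- mutant_pct / wildtype_pct
  data.frame(fold_change = fc,
             class = ifelse(fc > enhancer_threshold, "enhancer",
                     ifelse(fc < suppressor_threshold, "suppressor",
                            "neither")))
}

#' Copper-adaptation area under the dose-response curve
#'
#' Area under the curve of culture density (OD) against CuSO4 concentration,
#' integrated by the trapezoidal rule over the measured concentration range
#' (no extrapolation). Larger areas indicate greater copper tolerance.
#'
#' @param concentration strictly increasing concentrations (mM).
#' @param od culture densities (OD660, >= 0), same length.
#' @return area in OD*mM; attribute `rule` records the integration rule.
#' @export
adaptation_auc <- function(concentration, od) {
  if (length(concentration) < 2L)
    stop("need at least 2 dose-response points")
  stopifnot(length(concentration) == length(od))
  if (any(diff(concentration) <= 0))
    stop("concentrations must be strictly increasing")
  if (any(od < 0)) stop("OD values must be >= 0")
  structure(pracma::trapz(concentration, od), rule = "trapezoid")
}

#' Per-culture AUCs from a dose-response table
#'
#' @param dose_table data.frame with columns `sample`, `concentration`, `od`
#'   and optionally `group` (one measured series per sample).
#' @return data.frame `sample`, `group`, `auc`.
#' @export
auc_by_culture <- function(dose_table) {
  stopifnot(all(c("sample", "concentration", "od") %in% names(dose_table)))
  out <- do.call(rbind, lapply(split(dose_table, dose_table$sample), function(d) {
    d <- d[order(d$concentration), ]
    data.frame(sample = d$sample[1L],
               group = if (is.null(d$group)) NA_character_ else d$group[1L],
               auc = as.numeric(adaptation_auc(d$concentration, d$od)))
  }))
  rownames(out) <- NULL
  out
}

#' Import a 96-well plate of OD readings
#'
#' Reads a plate-reader export (rows A-H, columns 1-12) together with a plate
#' map assigning each well a sample, group and CuSO4 concentration, yielding
#' a tidy dose-response table for [auc_by_culture()].
#'
#' @param od_path TSV with a `row` column (A-H) and columns `1`..`12` of OD
#'   values.
#' @param map_path TSV with columns `well` (e.g. "A1"), `sample`,
#'   `concentration` and optionally `group`.
#' @param blank optional per-plate blank OD subtracted from every reading
#'   (negative results clipped at 0).
#' @return data.frame `well`, `sample`, `group`, `concentration`, `od`.
#' @export
read_plate <- function(od_path, map_path, blank = NULL) {
  od <- read.delim(od_path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- read.delim(map_path, stringsAsFactors = FALSE)
  stopifnot("row" %in% names(od),
            all(c("well", "sample", "concentration") %in% names(map)))
  long <- do.call(rbind, lapply(seq_len(nrow(od)), function(i) {
    cols <- setdiff(names(od), "row")
    data.frame(well = paste0(od$row[i], cols),
               od = as.numeric(od[i, cols]), stringsAsFactors = FALSE)
  }))
  out <- merge(map, long, by = "well", sort = FALSE)
  if (!is.null(blank)) out$od <- pmax(0, out$od - blank)
  if (is.null(out$group)) out$group <- NA_character_
  out[, c("well", "sample", "group", "concentration", "od")]
}

#' One-way ANOVA with Sidak-corrected pairwise comparisons
#'
#' Standard one-way ANOVA across groups followed by all pairwise comparisons
#' using the pooled error variance, with Sidak's multiple-comparison
#' correction: adjusted p = 1 - (1 - p)^m over the m comparisons performed.
#' Degenerate inputs (zero error variance) are handled without division
#' failure: identical groups give p = 1, separated groups p ~ 0.
#'
#' @param values numeric response values.
#' @param group group labels, same length (>= 2 groups, >= 2 values each).
#' @param correction `"sidak"` (default) or `"none"`.
#' @return list with `F` (statistic), `df` (c(between, within)), `p.value`
#'   (overall), and `pairwise` data.frame (`group1`, `group2`, `diff`, `t`,
#'   `p.raw`, `p.adj`).
#' @export
compare_groups <- function(values, group, correction = c("sidak", "none")) {
  correction <- match.arg(correction)
  group <- factor(group)
  stopifnot(length(values) == length(group))
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  if (any(table(group) < 2L)) stop("need >= 2 values per group")

  fit <- aov(values ~ group)
  tab <- suppressWarnings(anova(fit))   # perfect fits are handled below
  Fstat <- tab$`F value`[1L]
  p <- tab$`Pr(>F)`[1L]
  mse <- tab$`Mean Sq`[2L]
  dfw <- tab$Df[2L]
  if (!is.finite(Fstat)) {            # zero variance everywhere
    Fstat <- 0; p <- 1
  }

  lev <- levels(group)
  pairs <- utils::combn(lev, 2L)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    v1 <- values[group == g1]; v2 <- values[group == g2]
    d <- mean(v2) - mean(v1)
    se <- sqrt(mse * (1 / length(v1) + 1 / length(v2)))
    tstat <- if (se > 0) d / se else if (d == 0) 0 else sign(d) * Inf
    praw <- if (is.finite(tstat)) 2 * pt(-abs(tstat), dfw) else 0
    if (se == 0 && d == 0) praw <- 1
    data.frame(group1 = g1, group2 = g2, diff = d, t = tstat, p.raw = praw)
  }))
  pw$p.adj <- if (correction == "sidak") 1 - (1 - pw$p.raw)^m else pw$p.raw
  pw$p.adj <- pmin(1, pmax(pw$p.adj, pw$p.raw))
  list(F = Fstat, df = tab$Df, p.value = p, pairwise = pw,
       method = paste0("one-way ANOVA + pairwise t (pooled SE), ",
                       correction, " correction"))
}
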