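test_that("CNV percentage implements the band-intensity formula", {
  expect_equal(cnv_percent(100, "parental"), 0)
  expect_equal(cnv_percent(c(50, 50), c("parental", "cnv")), 50)
  # direct hand computation of the printed formula: 100 * (20+10)/(30+20+10)
  expect_equal(cnv_percent(c(30, 20, 10), c("parental", "cnv", "cnv")), 50)
  expect_error(cnv_percent(c(0, 0), c("parental", "cnv")), "zero total")
  expect_error(cnv_percent(c(1, 1), c("cnv", "cnv")), "parental")
})

test_that("CNV percentage is bounded and scale-invariant", {
  set.seed(15)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    int <- runif(k, 0.01, 100)
    cls <- c("parental", sample(c("parental", "cnv"), k - 1, TRUE))
    p <- cnv_percent(int, cls)
    expect_true(p >= 0 && p <= 100)
    expect_equal(cnv_percent(int * 7.3, cls), p, tolerance = 1e-12)
  }
})

test_that("screen fold change classifies enhancers and suppressors", {
  fc <- screen_fold_change(c(10, 25, 4), 10)
  expect_equal(fc$fold_change, c(1, 2.5, 0.4))
  expect_equal(fc$class, c("neither", "enhancer", "suppressor"))
  expect_error(screen_fold_change(10, 0), "> 0")
})

test_that("per-lane CNV summaries respect lane structure", {
  tab <- data.frame(
    sample = rep(c("wt", "mut"), each = 3),
    condition = "nic",
    band = rep(c("parental", "cnv1", "cnv2"), 2),
    intensity = c(80, 10, 10, 40, 30, 30),
    class = rep(c("parental", "cnv", "cnv"), 2))
  out <- cnv_table(tab)
  expect_equal(out$cnv_percent[out$sample == "wt"], 20)
  expect_equal(out$cnv_percent[out$sample == "mut"], 60)
  fc <- screen_fold_change(out$cnv_percent[out$sample == "mut"],
                           out$cnv_percent[out$sample == "wt"])
  expect_equal(fc$fold_change, 3)
  expect_equal(fc$class, "enhancer")
})

test_that("adaptation AUC follows the trapezoid rule without extrapolation", {
  expect_equal(as.numeric(adaptation_auc(c(0, 0.5), c(1, 1))), 0.5)
  expect_equal(as.numeric(adaptation_auc(seq(0, 1, 0.1), rep(0, 11))), 0)
  # closed-form triangle
  expect_equal(as.numeric(adaptation_auc(c(0, 0.5), c(1, 0))), 0.25)
  expect_error(adaptation_auc(0.5, 1), "at least 2")
  expect_error(adaptation_auc(c(0.5, 0.1), c(1, 1)), "increasing")
})

test_that("AUC is monotone under pointwise OD increase", {
  set.seed(16)
  for (i in 1:25) {
    conc <- sort(runif(6, 0, 1)); conc <- conc + seq(0, 0.5, 0.1)
    od <- runif(6, 0, 2)
    bump <- od + runif(6, 0, 0.5)
    expect_gte(as.numeric(adaptation_auc(conc, bump)),
               as.numeric(adaptation_auc(conc, od)))
  }
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  vals <- c(1, 2, 3, 4, 2, 3, 4, 5, 7, 8, 9, 10)
  grp <- rep(c("a", "b", "c"), each = 4)
  res <- compare_groups(vals, grp)
  # independent oracle: explicit between/within sums of squares
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ssb <- sum(4 * (means - gm)^2)
  ssw <- sum((vals - means[grp])^2)
  Foracle <- (ssb / 2) / (ssw / 9)
  expect_equal(res$F, Foracle)
  expect_equal(res$p.value, pf(Foracle, 2, 9, lower.tail = FALSE))
  # pairwise raw p agree with pooled-sd t tests from base R
  base_p <- pairwise.t.test(vals, grp, p.adjust.method = "none",
                            pool.sd = TRUE)$p.value
  expect_equal(res$pairwise$p.raw[1], base_p["b", "a"])
  expect_equal(res$pairwise$p.raw[2], base_p["c", "a"])
  expect_equal(res$pairwise$p.raw[3], base_p["c", "b"])
  # Sidak adjustment: 1 - (1 - p)^m, never below raw, bounded by 1
  expect_equal(res$pairwise$p.adj, 1 - (1 - res$pairwise$p.raw)^3)
  expect_true(all(res$pairwise$p.adj >= res$pairwise$p.raw))
  expect_true(all(res$pairwise$p.adj <= 1))
})

test_that("degenerate ANOVA inputs are handled without division failure", {
  res <- compare_groups(c(5, 5, 5, 5), c("a", "a", "b", "b"))
  expect_equal(res$F, 0)
  expect_equal(res$p.value, 1)
  expect_equal(res$pairwise$p.raw, 1)
  # identical group means but nonzero within-variance
  res2 <- compare_groups(c(1, 3, 1, 3), c("a", "a", "b", "b"))
  expect_equal(res2$F, 0)
  expect_equal(res2$p.value, 1)
})

test_that("dose-response tables and 96-well plates import to per-culture AUCs", {
  dr <- data.frame(sample = rep(c("s1", "s2"), each = 3),
                   group = rep(c("wt", "mut"), each = 3),
                   concentration = rep(c(0, 0.25, 0.5), 2),
                   od = c(1, 1, 1, 1, 0.5, 0))
  out <- auc_by_culture(dr)
  expect_equal(out$auc[out$sample == "s1"], 0.5)
  expect_equal(out$auc[out$sample == "s2"], 0.25)

  odf <- tempfile(fileext = ".tsv"); mapf <- tempfile(fileext = ".tsv")
  writeLines(c("row\t1\t2\t3", "A\t1.0\t0.8\t0.2", "B\t1.0\t0.9\t0.6"), odf)
  writeLines(c("well\tsample\tgroup\tconcentration",
               "A1\tc1\twt\t0", "A2\tc1\twt\t0.25", "A3\tc1\twt\t0.5",
               "B1\tc2\tmut\t0", "B2\tc2\tmut\t0.25", "B3\tc2\tmut\t0.5"),
             mapf)
  plate <- read_plate(odf, mapf)
  expect_equal(nrow(plate), 6L)
  aucs <- auc_by_culture(plate)
  expect_equal(aucs$auc[aucs$sample == "c1"],
               as.numeric(adaptation_auc(c(0, 0.25, 0.5), c(1, 0.8, 0.2))))
})

test_that("Sidak correction with a single comparison returns the raw p", {
  res <- compare_groups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(res$pairwise$p.adj, res$pairwise$p.raw)  # m = 1
})
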