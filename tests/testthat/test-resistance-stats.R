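test_that("noise-free 4PL data is refit exactly", {
  doses <- 10^seq(-1, 2, length.out = 8)
  dr <- generate_dose_response(3.3, 1, 100, 0, doses, noise_sd = 0,
                               replicates = 6)
  fit <- fit_dose_response(dr$dose_uM, dr$viability_pct)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 3.3, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)

  # steeper curve, shifted plateaus
  dr2 <- generate_dose_response(0.8, 2.5, 100, 20, doses, noise_sd = 0,
                                replicates = 3)
  fit2 <- fit_dose_response(dr2$dose_uM, dr2$viability_pct)
  expect_equal(fit2$ic50, 0.8, tolerance = 1e-6)
  expect_equal(fit2$top, 100, tolerance = 1e-4)
  expect_equal(fit2$bottom, 20, tolerance = 1e-4)

  # flat viability cannot converge
  flat <- fit_dose_response(doses, rep(100, 8))
  expect_false(flat$converged)

  expect_error(fit_dose_response(c(1, 2, 3), c(90, 50, 10)),
               "4 distinct doses")
  expect_error(fit_dose_response(c(-1, 1, 2, 3), c(99, 90, 50, 10)),
               "positive")
})

test_that("IC50 confidence intervals cover the truth at 5% noise", {
  doses <- 10^seq(-1, 1, length.out = 8) # two decades around the IC50
  cover <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    dr <- generate_dose_response(3.3, 1, 100, 0, doses, noise_sd = 5,
                                 replicates = 6, seed = s)
    f <- fit_dose_response(dr$dose_uM, dr$viability_pct)
    if (f$converged && f$ci_ic50[1] <= 3.3 && 3.3 <= f$ci_ic50[2]) {
      cover <- cover + 1
    }
  }
  expect_gte(cover / n_seeds, 0.9)
})

test_that("linear_fit matches closed-form OLS", {
  ex <- linear_fit(c(0, 1, 2, 3), c(1, 3, 5, 7)) # y = 2x + 1
  expect_equal(ex$slope, 2)
  expect_equal(ex$intercept, 1)
  expect_equal(ex$r_squared, 1)

  tri <- linear_fit(c(0, 1, 2), c(0, 1, 0))
  expect_equal(tri$slope, 0)
  expect_equal(tri$intercept, 1 / 3)
  expect_equal(tri$r_squared, 0)

  const <- linear_fit(c(1, 2, 3), c(4, 4, 4))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)
  expect_true(const$tss_zero)

  expect_error(linear_fit(c(1, 1, 1), c(1, 2, 3)), "degenerate design")
  expect_error(linear_fit(c(1, 2), c(1, 2)), "n >= 3")

  # random instances against the normal-equation closed form
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(7); y <- rnorm(7)
    f <- linear_fit(x, y)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(f$slope, slope, tolerance = 1e-12)
    expect_equal(f$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  }
})

test_that("ROC analysis equals brute-force pair counting and finds Youden", {
  r <- roc_analysis(c(0.1, 0.35, 0.3, 0.4), c("s", "s", "r", "r"),
                    positive = "r")
  expect_equal(r$auc, 0.75)

  ties <- roc_analysis(rep(0.3, 7), c(rep("s", 4), rep("r", 3)),
                       positive = "r")
  expect_equal(ties$auc, 0.5)

  sep <- roc_analysis(c(0.1, 0.2, 0.3, 0.6, 0.7),
                      c("s", "s", "s", "r", "r"), positive = "r")
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_equal(sep$threshold, 0.45) # midpoint of adjacent distinct scores

  expect_error(roc_analysis(1:3, rep("r", 3)), "both classes")

  # exhaustive small instances against the pair-counting oracle
  set.seed(15)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    labs <- c("s", "r", sample(c("s", "r"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # force ties
    r <- roc_analysis(scores, labs, positive = "r")
    expect_equal(r$auc, auc_brute_force(scores, labs, "r"))
    # invariance under strictly monotone transforms
    r2 <- roc_analysis(exp(3 * scores), labs, positive = "r")
    expect_equal(r2$auc, r$auc)
  }
})

test_that("ROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:10) {
    scores <- rnorm(20)
    labs <- sample(c("s", "r"), 20, replace = TRUE)
    if (length(unique(labs)) < 2) next
    ours <- roc_analysis(scores, labs, positive = "r")
    ref <- pROC::roc(response = labs, predictor = scores,
                     levels = c("s", "r"), direction = "<", quiet = TRUE)
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
  }
})

test_that("assay arithmetic follows the stated conventions", {
  # OCR: slope of fluorescence vs time per cell
  t <- c(0, 2, 4, 6)
  expect_equal(ocr_slope(t, 10 * t, n_cells = 5), 2)
  expect_equal(ocr_slope(t, rep(7, 4), n_cells = 5), 0)
  expect_error(ocr_slope(c(0, 2), c(1, 2), 5), "3 time points")
  expect_error(ocr_slope(t, 10 * t, 0), "positive")

  # FAO rate
  expect_equal(as.numeric(fao_rate(10, 4)), 6)
  expect_equal(as.numeric(fao_rate(4, 4)), 0)
  expect_warning(neg <- fao_rate(3, 4), "negative FAO")
  expect_equal(as.numeric(neg), -1)
  expect_true(attr(neg, "negative_flag"))

  # delta Ct: control minus target, higher = more expressed
  expect_equal(delta_ct(18, 20), 2)
  expect_equal(delta_ct(20, 20), 0)
  expect_equal(delta_ct(22, 20), -2)

  # tumor volume: l * w^2 / 2
  expect_equal(tumor_volume(2, 1), 1)
  expect_equal(tumor_volume(4, 3), 18)
  expect_equal(tumor_volume(0, 0), 0)
  expect_warning(sw <- tumor_volume(3, 4), "swapped")
  expect_equal(sw, 18)
  expect_error(tumor_volume(-1, 1), "non-negative")
})

test_that("group tests and respirometry metrics are computed correctly", {
  gt <- group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(gt$statistic, 0)
  expect_equal(gt$p_value, 1)
  far <- group_test(c(100, 101, 99, 100), c(1, 2, 1, 2))
  expect_lt(far$p_value, 1e-6)
  expect_error(group_test(1, c(1, 2)), "n >= 2")

  sm <- seahorse_metrics(c(10, 10, 10, 4, 4, 14, 14, 2, 2),
                         list(oligomycin = 4, fccp = 6, rotenone = 8))
  expect_equal(sm$non_mito, 2)
  expect_equal(sm$basal, 8)
  expect_equal(sm$atp_linked, 6)
  expect_equal(sm$maximal, 12)

  const <- seahorse_metrics(rep(5, 9),
                            list(oligomycin = 4, fccp = 6, rotenone = 8))
  expect_equal(const$basal, 0)
  expect_equal(const$atp_linked, 0)
  expect_equal(const$maximal, 0)
  expect_equal(const$non_mito, 5)

  expect_error(seahorse_metrics(rep(5, 9), list(oligomycin = 4,
                                                rotenone = 8)),
               "missing injection segment: fccp")

  red <- seahorse_reduction(sm, const)
  expect_equal(red$basal, 8)
  expect_equal(red$maximal, 12)
})
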