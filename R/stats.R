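#' Fit a four-parameter logistic dose-response curve
#'
#' Fits `viability = bottom + (top - bottom) / (1 + 10^(hill * (log10(dose)
#' - log10(ic50))))` — the 4PL model on log10 dose, equivalent to
#' `bottom + (top - bottom) / (1 + (dose/ic50)^hill)` — by bounded
#' Levenberg-Marquardt least squares with multi-start initialization from
#' the dose quantiles, so convergence is deterministic. IC50 is the dose at
#' half of (top + bottom). Bounds: top in \[50, 120\], bottom in
#' \[-10, 50\], hill in \[0.2, 5\] (viability in percent).
#'
#' @param doses Positive concentrations (at least 4 distinct values).
#' @param viabilities Viability percent, same length as `doses`.
#' @param ci `"asymptotic"` (t-interval on the log10 IC50 parameter;
#'   default) or `"bootstrap"` (case resampling within dose).
#' @param conf Confidence level for the IC50 interval.
#' @param n_boot Bootstrap replicates when `ci = "bootstrap"`.
#' @param seed Integer seed (bootstrap only).
#' @return Object of class `dose_response_fit`: `ic50`, `hill`, `top`,
#'   `bottom`, `rss`, `converged`, `ci_ic50`, `n`.
#' @export
fit_dose_response <- function(doses, viabilities,
                              ci = c("asymptotic", "bootstrap"),
                              conf = 0.95, n_boot = 200, seed = 1) {
  ci <- match.arg(ci)
  doses <- as.numeric(doses); viabilities <- as.numeric(viabilities)
  stopifnot(length(doses) == length(viabilities))
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(!is.finite(viabilities))) {
    stop("viabilities must be finite", call. = FALSE)
  }
  if (length(unique(doses)) < 4L) {
    stop("need at least 4 distinct doses", call. = FALSE)
  }
  failed <- function(msg) {
    structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                   bottom = NA_real_, rss = NA_real_, converged = FALSE,
                   ci_ic50 = c(NA_real_, NA_real_), n = length(doses),
                   diagnostics = msg),
              class = "dose_response_fit")
  }
  if (stats::sd(viabilities) < 1e-8) {
    return(failed("flat viability: plateaus not identifiable"))
  }
  ld <- log10(doses)
  lower <- c(top = 50, bottom = -10, hill = 0.2, lic50 = min(ld) - 2)
  upper <- c(top = 120, bottom = 50, hill = 5, lic50 = max(ld) + 2)
  model <- viabilities ~ bottom + (top - bottom) /
    (1 + 10^(hill * (ld - lic50)))
  dat <- data.frame(ld = ld, viabilities = viabilities)
  starts <- lapply(stats::quantile(ld, c(0.25, 0.5, 0.75)), function(q) {
    list(top = min(max(stats::quantile(viabilities, 0.95), 51), 119),
         bottom = min(max(stats::quantile(viabilities, 0.05), -9), 49),
         hill = 1, lic50 = unname(q))
  })
  best <- NULL
  for (st in starts) {
    f <- try(suppressWarnings(minpack.lm::nlsLM(
      model, data = dat, start = st, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (!inherits(f, "try-error")) {
      rss <- sum(stats::residuals(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best)) return(failed("no start converged"))
  cf <- stats::coef(best$fit)
  if (cf[["top"]] - cf[["bottom"]] < 1e-6) {
    return(failed("degenerate fit: top == bottom"))
  }
  # gross monotonicity check on dose-averaged viability
  mu <- tapply(viabilities, doses, mean)
  if (stats::cor(as.numeric(names(mu)), mu, method = "spearman") > 0.5) {
    warning("viability increases with dose: check data orientation")
  }
  ci_ic50 <- c(NA_real_, NA_real_)
  if (ci == "asymptotic") {
    se <- try(summary(best$fit)$coefficients["lic50", "Std. Error"],
              silent = TRUE)
    if (!inherits(se, "try-error") && is.finite(se)) {
      df <- length(doses) - 4L
      tq <- stats::qt(1 - (1 - conf) / 2, df)
      ci_ic50 <- 10^(cf[["lic50"]] + c(-1, 1) * tq * se)
    }
  } else {
    set.seed(seed)
    idx_by_dose <- split(seq_along(doses), doses)
    bstats <- replicate(n_boot, {
      take <- unlist(lapply(idx_by_dose, function(ii) {
        sample(ii, length(ii), replace = TRUE)
      }), use.names = FALSE)
      bf <- try(suppressWarnings(minpack.lm::nlsLM(
        model, data = dat[take, ], start = as.list(cf),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 100))),
        silent = TRUE)
      if (inherits(bf, "try-error")) NA_real_ else
        stats::coef(bf)[["lic50"]]
    })
    alpha <- (1 - conf) / 2
    ci_ic50 <- 10^unname(stats::quantile(bstats, c(alpha, 1 - alpha),
                                         na.rm = TRUE))
  }
  structure(
    list(ic50 = unname(10^cf[["lic50"]]), hill = unname(cf[["hill"]]),
         top = unname(cf[["top"]]), bottom = unname(cf[["bottom"]]),
         rss = best$rss, converged = TRUE, ci_ic50 = ci_ic50,
         n = length(doses), diagnostics = "ok"),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<dose_response_fit> not converged:", x$diagnostics, "\n")
  } else {
    cat(sprintf(
      "<dose_response_fit> IC50 = %.4g [%.4g, %.4g], hill = %.3g, top = %.4g, bottom = %.4g\n",
      x$ic50, x$ci_ic50[1], x$ci_ic50[2], x$hill, x$top, x$bottom))
  }
  invisible(x)
}

#' Ordinary least-squares linear fit
#'
#' Simple regression used to relate per-sample metabolic index to IC50;
#' `R^2 = 1 - RSS/TSS`. When y is constant (TSS = 0) the slope is 0 and
#' R^2 is defined as 0 with a flag.
#'
#' @param x,y Numeric vectors, n >= 3; `x` must not be constant.
#' @return List: `slope`, `intercept`, `r_squared`, `n`, `p_value`,
#'   `tss_zero` flag.
#' @export
linear_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate design: x is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                n = length(x), p_value = NA_real_, tss_zero = TRUE))
  }
  rss <- sum(stats::residuals(fit)^2)
  # summary() warns on exact fits ("essentially perfect fit"); the slope
  # p-value is still well-defined for our use
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - rss / tss, n = length(x),
       p_value = unname(sm$coefficients[2, 4]), tss_zero = FALSE)
}

#' ROC analysis of a resistance score
#'
#' Treats resistant as the positive class with higher scores indicating
#' resistance. AUC is the rank (Mann-Whitney) statistic with 0.5 credit
#' for ties; the operating threshold maximizes Youden's J = sensitivity +
#' specificity - 1 and is reported as the midpoint between the adjacent
#' distinct scores.
#'
#' @param scores Numeric scores (e.g. per-sample mean metabolic index).
#' @param labels Class labels containing both classes.
#' @param positive Label of the positive (resistant) class.
#' @return Object of class `roc_result`: `auc`, `threshold`,
#'   `sensitivity`, `specificity`, `youden_j`, `curve` (data frame of all
#'   candidate thresholds with sensitivity/specificity).
#' @export
roc_analysis <- function(scores, labels, positive = "resistant") {
  scores <- as.numeric(scores)
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores) # midranks: ties get 0.5 credit
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  u <- sort(unique(scores))
  thr <- if (length(u) > 1L) {
    c(u[1] - 1, (utils::head(u, -1) + utils::tail(u, -1)) / 2, u[length(u)] + 1)
  } else {
    c(u - 1, u + 1)
  }
  sens <- vapply(thr, function(t) sum(scores > t & pos) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(scores <= t & !pos) / n_neg, 0)
  j <- sens + spec - 1
  best <- which.max(j)
  structure(
    list(auc = auc, threshold = thr[best], sensitivity = sens[best],
         specificity = spec[best], youden_j = j[best],
         curve = data.frame(threshold = thr, sensitivity = sens,
                            specificity = spec)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f; threshold = %.4g (sens %.2f, spec %.2f)\n",
    x$auc, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Oxygen consumption rate from a fluorescence trace
#'
#' OCR expressed as the change in fluorescence intensity per minute per
#' cell: the least-squares slope of fluorescence against time, divided by
#' the cell count.
#'
#' @param time_min Time points in minutes (>= 3).
#' @param fluorescence Fluorescence intensities.
#' @param n_cells Number of cells in the well (> 0).
#' @return OCR in delta-fluorescence / min / cell.
#' @export
ocr_slope <- function(time_min, fluorescence, n_cells) {
  if (length(time_min) < 3L) {
    stop("need at least 3 time points", call. = FALSE)
  }
  if (n_cells <= 0) stop("`n_cells` must be positive", call. = FALSE)
  stopifnot(length(time_min) == length(fluorescence))
  unname(stats::coef(stats::lm(fluorescence ~ time_min))[2]) / n_cells
}

#' Fatty-acid oxidation rate
#'
#' `OCR_FAO = OCR_total - OCR_etomoxir` (etomoxir blocks CPT1-mediated
#' fatty-acid import into mitochondria). Negative rates are biologically
#' impossible but returned with a warning — informative for QC.
#'
#' @param ocr_total,ocr_etomoxir Finite OCR values.
#' @return The difference, with attribute `negative_flag`.
#' @export
fao_rate <- function(ocr_total, ocr_etomoxir) {
  stopifnot(is.finite(ocr_total), is.finite(ocr_etomoxir))
  out <- ocr_total - ocr_etomoxir
  flag <- out < 0
  if (flag) warning("negative FAO rate: OCR_etomoxir exceeds OCR_total")
  attr(out, "negative_flag") <- flag
  out
}

#' qPCR delta-Ct expression measure
#'
#' `delta_Ct = Ct(control) - Ct(target)`, so that higher values mean more
#' target expression.
#'
#' @param ct_target,ct_control Finite cycle-threshold values.
#' @return delta-Ct (vectorized).
#' @export
delta_ct <- function(ct_target, ct_control) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_control)))
  ct_control - ct_target
}

#' Caliper tumor volume
#'
#' `volume = length * width^2 / 2` (mm^3). If width exceeds length the
#' two are swapped with a warning (the formula assumes length >= width).
#'
#' @param length_mm,width_mm Non-negative caliper measurements.
#' @return Volume in mm^3 (vectorized).
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0)) {
    stop("measurements must be non-negative", call. = FALSE)
  }
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width > length for ", sum(swap), " measurement(s); swapped")
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  length_mm * width_mm^2 / 2
}

#' Two-sample Student's t test
#'
#' Pooled-variance Student's t by default (Welch optional), one- or
#' two-sided.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param sides `"two.sided"`, `"less"` or `"greater"` (alternative for
#'   `a` relative to `b`).
#' @param equal_var Pooled variance (TRUE, Student) or Welch (FALSE).
#' @return List: `statistic`, `p_value`, `df`.
#' @export
group_test <- function(a, b, sides = c("two.sided", "less", "greater"),
                       equal_var = TRUE) {
  sides <- match.arg(sides)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  tt <- stats::t.test(a, b, alternative = sides, var.equal = equal_var)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Mitochondrial respiration metrics from a Seahorse-style OCR trace
#'
#' Standard convention for an oligomycin / FCCP / rotenone+antimycin
#' injection sequence: non-mitochondrial respiration is the mean after
#' rotenone/antimycin; basal = last pre-injection value minus non-mito;
#' ATP-linked = basal minus (post-oligomycin mean minus non-mito);
#' maximal = post-FCCP mean minus non-mito.
#'
#' @param ocr_trace Numeric OCR measurements in acquisition order.
#' @param injection_indices Named list/vector with `oligomycin`, `fccp`,
#'   `rotenone`: index of the first measurement after each injection.
#' @return List: `non_mito`, `basal`, `atp_linked`, `maximal`.
#' @export
seahorse_metrics <- function(ocr_trace, injection_indices) {
  need <- c("oligomycin", "fccp", "rotenone")
  for (nm in need) {
    if (is.null(injection_indices[[nm]]) || is.na(injection_indices[[nm]])) {
      stop("missing injection segment: ", nm, call. = FALSE)
    }
  }
  io <- as.integer(injection_indices[["oligomycin"]])
  if_ <- as.integer(injection_indices[["fccp"]])
  ir <- as.integer(injection_indices[["rotenone"]])
  n <- length(ocr_trace)
  if (!(1L < io && io < if_ && if_ < ir && ir <= n)) {
    stop("injection indices must be ordered within the trace", call. = FALSE)
  }
  seg_oligo <- ocr_trace[io:(if_ - 1L)]
  seg_fccp <- ocr_trace[if_:(ir - 1L)]
  seg_rot <- ocr_trace[ir:n]
  non_mito <- mean(seg_rot)
  basal <- ocr_trace[io - 1L] - non_mito
  atp_linked <- basal - (mean(seg_oligo) - non_mito)
  maximal <- mean(seg_fccp) - non_mito
  list(non_mito = non_mito, basal = basal, atp_linked = atp_linked,
       maximal = maximal)
}

#' Treatment-induced reduction of respiration metrics
#'
#' `reduction = metric(control) - metric(treated)` for each metric shared
#' by the two [seahorse_metrics()] results (e.g. etomoxir-induced basal,
#' ATP-linked and maximal respiration reduction).
#'
#' @param metrics_control,metrics_treated Results of [seahorse_metrics()].
#' @return Named list of reductions.
#' @export
seahorse_reduction <- function(metrics_control, metrics_treated) {
  nm <- intersect(names(metrics_control), names(metrics_treated))
  stats::setNames(
    lapply(nm, function(x) metrics_control[[x]] - metrics_treated[[x]]), nm)
}
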