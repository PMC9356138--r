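#' Draw per-cell intensities from a log-normal mixture
#'
#' Emulates the bimodal per-cell integrated lipid intensity histograms seen
#' in single-cell SRS analysis, where lipid-poor and lipid-rich
#' subpopulations coexist in one line.
#'
#' @param weights Mixture weights, must sum to 1 (tolerance 1e-9).
#' @param log_means Per-component means on the log-intensity scale.
#' @param log_sd Standard deviation on the log scale; scalar or one value
#'   per component.
#' @param n Number of cells to draw (`n = 0` gives empty outputs).
#' @param seed Integer seed; all randomness in this call derives from it.
#' @return List with `intensity` (positive numeric, length `n`) and
#'   `class` (integer component labels, for recovery tests).
#' @export
generate_population_intensities <- function(weights, log_means, log_sd,
                                            n, seed = 1) {
  weights <- as.numeric(weights)
  log_means <- as.numeric(log_means)
  if (length(weights) != length(log_means)) {
    stop("`weights` and `log_means` must have the same length", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("invalid weights: must be non-negative and sum to 1", call. = FALSE)
  }
  log_sd <- rep_len(as.numeric(log_sd), length(weights))
  if (any(log_sd < 0)) stop("`log_sd` must be >= 0", call. = FALSE)
  n <- as.integer(n)
  if (n == 0L) {
    return(list(intensity = numeric(0), class = integer(0)))
  }
  if (n < 0L) stop("`n` must be >= 0", call. = FALSE)
  set.seed(seed)
  cls <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  intensity <- exp(stats::rnorm(n, mean = log_means[cls], sd = log_sd[cls]))
  list(intensity = intensity, class = cls)
}

#' Simulate a 4-parameter logistic dose-response experiment
#'
#' Viability follows
#' `bottom + (top - bottom) / (1 + (dose / ic50)^hill)` with additive
#' Gaussian noise, replicated as in a plate-based viability assay
#' (six replicates per dose by default).
#'
#' @param ic50 Half-maximal inhibitory concentration (same units as
#'   `doses`, typically uM).
#' @param hill Hill slope (> 0 for a decreasing curve in dose).
#' @param top,bottom Upper and lower viability plateaus (percent);
#'   `top > bottom` required.
#' @param doses Vector of positive concentrations.
#' @param noise_sd Gaussian noise SD in viability percent.
#' @param replicates Replicates per dose.
#' @param seed Integer seed.
#' @return Data frame with columns `dose_uM`, `viability_pct`, `replicate`.
#' @export
generate_dose_response <- function(ic50, hill, top, bottom, doses,
                                   noise_sd = 0, replicates = 6, seed = 1) {
  doses <- as.numeric(doses)
  if (any(doses <= 0) || any(!is.finite(doses))) {
    stop("all doses must be positive and finite", call. = FALSE)
  }
  if (ic50 <= 0) stop("`ic50` must be positive", call. = FALSE)
  if (!(top > bottom)) stop("`top` must exceed `bottom`", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  set.seed(seed)
  d <- rep(doses, each = replicates)
  mu <- bottom + (top - bottom) / (1 + (d / ic50)^hill)
  v <- mu + stats::rnorm(length(d), sd = noise_sd)
  data.frame(
    dose_uM = d,
    viability_pct = v,
    replicate = rep(seq_len(replicates), times = length(doses))
  )
}

#' Simulate a resistance cohort of per-cell metabolic indices
#'
#' Draws per-cell metabolic indices for sensitive and resistant samples
#' from truncated normal distributions on \[0, 1\] (truncation by
#' resampling, preserving the index's domain) and summarises each sample
#' by its mean index and SEM — one data point per sample, mirroring
#' per-patient averages of single-cell indices.
#'
#' @param n_sensitive,n_resistant Number of samples per group (>= 1).
#' @param mean_s,mean_r Group mean index, each in (0, 1).
#' @param sd Per-cell index SD (common to both groups).
#' @param cells_per_sample Cells imaged per sample.
#' @param seed Integer seed.
#' @return List with `samples` (sample_id, label, mean_index, sem,
#'   n_cells) and `cells` (sample_id, label, index).
#' @export
generate_cohort <- function(n_sensitive, n_resistant, mean_s, mean_r,
                            sd = 0.04, cells_per_sample = 30, seed = 1) {
  n_sensitive <- as.integer(n_sensitive)
  n_resistant <- as.integer(n_resistant)
  if (n_sensitive < 1L || n_resistant < 1L) {
    stop("group sizes must be >= 1", call. = FALSE)
  }
  for (m in c(mean_s, mean_r)) {
    if (!is.finite(m) || m <= 0 || m >= 1) {
      stop("group means must lie strictly inside (0, 1)", call. = FALSE)
    }
  }
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  cells_per_sample <- as.integer(cells_per_sample)
  stopifnot(cells_per_sample >= 1L)
  set.seed(seed)

  draw_cells <- function(mu) {
    x <- stats::rnorm(cells_per_sample, mu, sd)
    bad <- which(x < 0 | x > 1)
    guard <- 0L
    while (length(bad) > 0L && guard < 1000L) {
      x[bad] <- stats::rnorm(length(bad), mu, sd)
      bad <- which(x < 0 | x > 1)
      guard <- guard + 1L
    }
    if (length(bad) > 0L) x[bad] <- pmin(pmax(x[bad], 0), 1)
    x
  }

  labels <- c(rep("sensitive", n_sensitive), rep("resistant", n_resistant))
  sample_id <- sprintf("%s_%02d", substr(labels, 1, 1),
                       c(seq_len(n_sensitive), seq_len(n_resistant)))
  cells <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    mu <- if (labels[i] == "sensitive") mean_s else mean_r
    cells[[i]] <- data.frame(
      sample_id = sample_id[i], label = labels[i],
      index = draw_cells(mu)
    )
  }
  cells <- do.call(rbind, cells)
  samples <- do.call(rbind, lapply(split(cells, cells$sample_id), function(d) {
    agg <- aggregate_sample(d$index)
    data.frame(sample_id = d$sample_id[1], label = d$label[1],
               mean_index = agg$mean, sem = agg$sem, n_cells = agg$n)
  }))
  samples <- samples[match(sample_id, samples$sample_id), ]
  rownames(samples) <- NULL
  rownames(cells) <- NULL
  list(samples = samples, cells = cells)
}
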