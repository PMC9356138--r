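#' Quantify per-cell lipid/probe metrics
#'
#' For each retained cell and each named signal image, computes the
#' integrated intensity (sum over the cell's signal pixels — the pixels of
#' that component above `signal_floor`, i.e. the component map masked onto
#' the outlined cell), the mean intensity (integrated / number of signal
#' pixels; defined as 0 with a flag when a cell has no signal pixels), and
#' the signal area fraction (signal pixels / cell area). Droplet count and
#' mean droplet size come from the droplet assignment table.
#'
#' @param cell_labels Integer cell label matrix.
#' @param signal_images Named list of intensity matrices on the same grid
#'   (e.g. `list(CH = lipid_map)` or `list(CC = ..., CD = ...)`).
#' @param droplet_to_cell Optional droplet assignment data frame from
#'   [detect_droplets()].
#' @param exclude_edge_cells Drop cells touching the image border
#'   (truncated cells bias per-cell intensity histograms).
#' @param signal_floor Intensity above which a pixel counts as signal.
#' @return Data frame, one row per retained cell: `cell_id`, `area_px`,
#'   then per image `integrated_<name>`, `mean_<name>`,
#'   `area_fraction_<name>`, `zero_signal_<name>`, plus `droplet_count`
#'   and `mean_droplet_size_px`.
#' @export
quantify_cells <- function(cell_labels, signal_images,
                           droplet_to_cell = NULL,
                           exclude_edge_cells = TRUE, signal_floor = 0) {
  for (img in signal_images) {
    if (!identical(dim(img), dim(cell_labels))) {
      stop("signal images must share the label grid", call. = FALSE)
    }
  }
  ids <- sort(unique(cell_labels[cell_labels > 0L]))
  if (exclude_edge_cells) ids <- setdiff(ids, edge_cells(cell_labels))
  out <- data.frame(cell_id = ids)
  fac <- factor(cell_labels, levels = ids)
  out$area_px <- as.integer(table(fac))
  for (nm in names(signal_images)) {
    img <- signal_images[[nm]]
    sig <- img > signal_floor
    n_sig <- vapply(ids, function(i) sum(sig[cell_labels == i]), 0L)
    integ <- vapply(ids, function(i) sum(img[cell_labels == i & sig]), 0)
    out[[paste0("integrated_", nm)]] <- integ
    out[[paste0("mean_", nm)]] <- ifelse(n_sig > 0L, integ / n_sig, 0)
    out[[paste0("zero_signal_", nm)]] <- n_sig == 0L
    out[[paste0("area_fraction_", nm)]] <- n_sig / out$area_px
  }
  if (!is.null(droplet_to_cell) && nrow(droplet_to_cell) > 0L) {
    agg_n <- table(factor(droplet_to_cell$cell_id, levels = ids))
    out$droplet_count <- as.integer(agg_n)
    mean_sz <- tapply(droplet_to_cell$area_px,
                      factor(droplet_to_cell$cell_id, levels = ids), mean)
    out$mean_droplet_size_px <- as.numeric(ifelse(is.na(mean_sz), 0, mean_sz))
  } else {
    out$droplet_count <- 0L
    out$mean_droplet_size_px <- 0
  }
  rownames(out) <- NULL
  out
}

#' Histogram of a per-cell metric
#'
#' Freedman-Diaconis binning by default; pass explicit `breaks` to share
#' bins across compared groups.
#'
#' @param values Numeric vector (n >= 1).
#' @param breaks Bin specification as in [graphics::hist()]; default
#'   `"FD"`.
#' @return Data frame with `lo`, `hi`, `mid`, `count`; bin edges as
#'   attribute `"breaks"`. Counts sum to `length(values)`.
#' @export
population_histogram <- function(values, breaks = "FD") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty input", call. = FALSE)
  if (diff(range(values)) == 0) {
    # constant input: one bin holds everything
    breaks <- values[1] + c(-0.5, 0.5)
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  out <- data.frame(lo = utils::head(h$breaks, -1),
                    hi = utils::tail(h$breaks, -1),
                    mid = h$mids, count = h$counts)
  attr(out, "breaks") <- h$breaks
  out
}

#' Detect lipid-poor and lipid-rich subpopulations
#'
#' Fits Gaussian mixtures on the log-intensity scale for each candidate
#' number of components and selects k by BIC. When two components are
#' selected, the lower-mean component is labelled `lipid-poor` and the
#' higher-mean one `lipid-rich`; cells are classified by maximum
#' posterior. Because the fit acts on log intensities, the classification
#' is invariant to global intensity scaling.
#'
#' @param intensities Positive per-cell intensities, n >= 10.
#' @param k_candidates Candidate component counts (default 1..4).
#' @param seed Integer seed.
#' @return Object of class `subpop_fit`: `k_selected`, `weights`, `means`,
#'   `sds` (log scale, ordered by mean), `class` (per-cell labels),
#'   `posterior`, `bic` (per candidate k).
#' @export
classify_subpopulations <- function(intensities, k_candidates = 1:4,
                                    seed = 1) {
  x <- as.numeric(intensities)
  if (length(x) < 10L) {
    stop("insufficient data: need at least 10 cells", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("intensities must be positive (log scale undefined otherwise)",
         call. = FALSE)
  }
  set.seed(seed)
  lx <- log(x)
  fit <- mclust::Mclust(lx, G = k_candidates, modelNames = c("E", "V"),
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  k <- fit$G
  means <- fit$parameters$mean
  sds <- sqrt(rep_len(fit$parameters$variance$sigmasq, k))
  weights <- fit$parameters$pro
  ord <- order(means)
  means <- means[ord]; sds <- sds[ord]; weights <- weights[ord]
  post <- fit$z[, ord, drop = FALSE]
  cls_idx <- max.col(post, ties.method = "first")
  comp_names <- if (k == 2L) c("lipid-poor", "lipid-rich") else
    paste0("component", seq_len(k))
  colnames(post) <- comp_names
  bic_tab <- fit$BIC
  structure(
    list(k_selected = k, weights = unname(weights), means = unname(means),
         sds = unname(sds), class = comp_names[cls_idx], posterior = post,
         bic = bic_tab, criterion = "BIC"),
    class = "subpop_fit"
  )
}

#' @export
print.subpop_fit <- function(x, ...) {
  cat("<subpop_fit> k =", x$k_selected, "by", x$criterion, "\n")
  cat("  weights:", round(x$weights, 3), "\n")
  cat("  log-means:", round(x$means, 3), "\n")
  invisible(x)
}

#' Compare lipid subpopulations between two cell tables
#'
#' Classifies the pooled metric (shared two-component mixture on pooled
#' log intensities, so the poor/rich boundary is common to both groups),
#' reports each group's lipid-rich fraction, their difference with a
#' bootstrap confidence interval, and a two-sample test on the metric.
#'
#' @param table_a,table_b CellTable data frames from [quantify_cells()].
#' @param metric Column name to compare (e.g. `"integrated_CH"`).
#' @param n_boot Bootstrap replicates for the CI on the fraction
#'   difference.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return List: `fraction_rich_a`, `fraction_rich_b`, `difference`
#'   (b - a), `ci` (bootstrap percentile), `test` (Welch t on log metric).
#' @export
compare_populations <- function(table_a, table_b, metric, n_boot = 1000,
                                conf = 0.95, seed = 1) {
  if (nrow(table_a) == 0L || nrow(table_b) == 0L) {
    stop("both tables must be non-empty", call. = FALSE)
  }
  if (!metric %in% names(table_a) || !metric %in% names(table_b)) {
    stop("unknown metric: '", metric, "'", call. = FALSE)
  }
  a <- table_a[[metric]]; b <- table_b[[metric]]
  if (any(c(a, b) <= 0)) {
    stop("metric values must be positive for mixture classification",
         call. = FALSE)
  }
  pooled <- c(a, b)
  fit <- classify_subpopulations(pooled, k_candidates = 2, seed = seed)
  # classify by the shared posterior boundary on log intensity
  boundary_class <- function(x) {
    # posterior of "rich" component under the pooled fit
    d_poor <- fit$weights[1] * stats::dnorm(log(x), fit$means[1], fit$sds[1])
    d_rich <- fit$weights[2] * stats::dnorm(log(x), fit$means[2], fit$sds[2])
    d_rich > d_poor
  }
  rich_a <- boundary_class(a); rich_b <- boundary_class(b)
  fa <- mean(rich_a); fb <- mean(rich_b)
  set.seed(seed)
  boot <- replicate(n_boot, {
    mean(sample(rich_b, replace = TRUE)) -
      mean(sample(rich_a, replace = TRUE))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  tt <- stats::t.test(log(b), log(a))
  list(fraction_rich_a = fa, fraction_rich_b = fb,
       difference = fb - fa, ci = ci,
       test = list(statistic = unname(tt$statistic),
                   p_value = tt$p.value, method = tt$method))
}
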