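#' Compute the metabolic index
#'
#' The metabolic index is `M = F / (F + G)` where `F` is the fatty-acid
#' uptake signal (deuterated fatty acid C-D metric, or the alkyne C-C
#' metric of an ODYA tracer in dual-probe mode) and `G` the glucose-derived
#' anabolism signal (glucose-d7 C-D metric), both measured on the same
#' per-cell metric. M is dimensionless, lies in \[0, 1\], increases
#' strictly in F and decreases strictly in G, and is invariant to a common
#' positive scaling of F and G (robust to global imaging-power changes).
#' Higher M tracks platinum resistance.
#'
#' @param F_signal,G_signal Non-negative signals (vectorized).
#' @return Numeric vector of indices in \[0, 1\]; cells with
#'   `F + G == 0` carry an undefined index, returned as `NA` with a
#'   warning (they are excluded, never silently set to 0).
#' @export
compute_index <- function(F_signal, G_signal) {
  F_signal <- as.numeric(F_signal); G_signal <- as.numeric(G_signal)
  if (length(F_signal) != length(G_signal)) {
    stop("`F_signal` and `G_signal` must have the same length", call. = FALSE)
  }
  if (any(F_signal < 0, na.rm = TRUE) || any(G_signal < 0, na.rm = TRUE)) {
    stop("signals must be non-negative", call. = FALSE)
  }
  tot <- F_signal + G_signal
  undefined <- tot == 0
  m <- ifelse(undefined, NA_real_, F_signal / tot)
  if (any(undefined, na.rm = TRUE)) {
    warning(sum(undefined, na.rm = TRUE),
            " cell(s) with F + G = 0: index undefined (NA)")
  }
  m
}

#' Per-cell metabolic index from dual-probe component images
#'
#' Measures, per outlined cell, the fatty-acid tracer signal (C-C image)
#' and the glucose-derived signal (C-D image) on a common metric and forms
#' the metabolic index. The default metric is the signal area fraction
#' (fraction of cell pixels where the component exceeds its floor), the
#' convention for C-D quantification; mean and integrated intensity are
#' available since intensity-based quantification is also standard.
#'
#' @param cc_image,cd_image Component abundance or intensity matrices
#'   (from [map_clusters_to_images()] or [unmix_dual_probe()]).
#' @param cell_labels Integer cell label matrix on the same grid.
#' @param metric `"area_fraction"`, `"mean_intensity"` or `"integrated"`.
#' @param floors Named vector `c(cc = ..., cd = ...)`: per-image signal
#'   floors.
#' @param exclude_edge_cells Drop border-touching cells.
#' @return List: `per_cell` (cell_id, F, G, M), `summary`
#'   ([aggregate_sample()] of the defined indices), `n_excluded` (cells
#'   with undefined index, i.e. neither probe above floor).
#' @export
index_from_dual_probe <- function(cc_image, cd_image, cell_labels,
                                  metric = c("area_fraction",
                                             "mean_intensity", "integrated"),
                                  floors = c(cc = 0, cd = 0),
                                  exclude_edge_cells = TRUE) {
  metric <- match.arg(metric)
  if (!identical(dim(cc_image), dim(cell_labels)) ||
      !identical(dim(cd_image), dim(cell_labels))) {
    stop("images and labels must share the same grid", call. = FALSE)
  }
  tab <- quantify_cells(cell_labels,
                        list(cc = cc_image, cd = cd_image),
                        exclude_edge_cells = exclude_edge_cells,
                        signal_floor = 0)
  # recompute with per-image floors
  ids <- tab$cell_id
  col <- switch(metric, area_fraction = "area_fraction_",
                mean_intensity = "mean_", integrated = "integrated_")
  measure <- function(img, floor_v) {
    sig <- img > floor_v
    n_sig <- vapply(ids, function(i) sum(sig[cell_labels == i]), 0L)
    integ <- vapply(ids, function(i) sum(img[cell_labels == i & sig]), 0)
    switch(metric,
           area_fraction = n_sig / tab$area_px,
           mean_intensity = ifelse(n_sig > 0L, integ / n_sig, 0),
           integrated = integ)
  }
  F_sig <- measure(cc_image, floors[["cc"]])
  G_sig <- measure(cd_image, floors[["cd"]])
  m <- suppressWarnings(compute_index(F_sig, G_sig))
  defined <- !is.na(m)
  per_cell <- data.frame(cell_id = ids, F = F_sig, G = G_sig, M = m)
  list(per_cell = per_cell,
       summary = if (any(defined)) aggregate_sample(m[defined]) else NULL,
       n_excluded = sum(!defined), metric = metric)
}

#' Aggregate per-cell indices to a sample summary
#'
#' Per-sample index = arithmetic mean of per-cell indices (the
#' per-patient convention: one averaged index per sample), with
#' `SEM = sd / sqrt(n)` (sample sd, n - 1 denominator). With a single
#' cell the SEM is 0 and flagged.
#'
#' @param per_cell_m Numeric vector of per-cell indices, n >= 1.
#' @return List: `mean`, `sem`, `n`, `sem_flagged` (TRUE when n = 1).
#' @export
aggregate_sample <- function(per_cell_m) {
  x <- as.numeric(per_cell_m)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1L) stop("empty input: no defined indices", call. = FALSE)
  if (n == 1L) {
    return(list(mean = x, sem = 0, n = 1L, sem_flagged = TRUE))
  }
  list(mean = mean(x), sem = stats::sd(x) / sqrt(n), n = n,
       sem_flagged = FALSE)
}
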