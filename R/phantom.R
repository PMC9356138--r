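#' Specify a hyperspectral cell phantom
#'
#' Defines the geometry, chemistry and noise of a synthetic field of
#' cells: non-overlapping disc cells with a nucleus, cytoplasm and lipid
#' droplets, each compartment carrying its own mixture of component
#' spectra. A two-class population mixture (lipid-poor / lipid-rich)
#' scales droplet abundances per cell, producing the bimodal per-cell
#' lipid distributions seen in resistant/sensitive cell lines.
#'
#' @param image_shape `(rows, cols)` in pixels.
#' @param n_channels Number of spectral channels (50-image stacks are the
#'   acquisition convention emulated here).
#' @param wavenumber_range `(lo, hi)` cm^-1 of the acquired window (C-H:
#'   2800-3050; C-D: 2050-2350).
#' @param n_cells Number of cells to place.
#' @param cell_radius_range `(min, max)` cell radius in pixels.
#' @param nucleus_radius_fraction Nucleus radius as a fraction of the cell
#'   radius, in (0, 1).
#' @param droplets_per_cell Mean of the Poisson droplet count per cell.
#' @param droplet_radius_range `(min, max)` droplet radius in pixels.
#' @param components Named list of [spectral_component()]s.
#' @param abundances Named list with elements `nucleus`, `cytoplasm`,
#'   `droplet`, each a named numeric vector of component weights.
#' @param population_mixture List with `fractions` (named, sums to 1) and
#'   `droplet_scale` (same names): per-class droplet abundance scaling.
#' @param noise `(shot_scale, gaussian_sd)`: the rendered pixel gets
#'   Gaussian noise of sd `shot_scale * sqrt(signal)` (photon-shot-like)
#'   plus additive Gaussian noise of sd `gaussian_sd`.
#' @param pixel_size um/pixel.
#' @param seed Integer seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(192L, 192L),
                         n_channels = 50L,
                         wavenumber_range = c(2800, 3050),
                         n_cells = 12L,
                         cell_radius_range = c(12, 16),
                         nucleus_radius_fraction = 0.35,
                         droplets_per_cell = 3,
                         droplet_radius_range = c(2.5, 3.5),
                         components = default_components()[c("CH_protein",
                                                             "CH_lipid")],
                         abundances = list(
                           nucleus = c(CH_protein = 1),
                           cytoplasm = c(CH_protein = 0.7, CH_lipid = 0.3),
                           droplet = c(CH_lipid = 1)),
                         population_mixture = list(
                           fractions = c(poor = 0.5, rich = 0.5),
                           droplet_scale = c(poor = 1, rich = 10)),
                         noise = c(shot_scale = 0.02, gaussian_sd = 0.01),
                         pixel_size = 0.5,
                         seed = 1L) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1L))
  if (n_channels < 2L) stop("`n_channels` must be >= 2", call. = FALSE)
  if (nucleus_radius_fraction <= 0 || nucleus_radius_fraction >= 1) {
    stop("`nucleus_radius_fraction` must be in (0, 1)", call. = FALSE)
  }
  fr <- population_mixture$fractions
  if (abs(sum(fr) - 1) > 1e-9 || any(fr < 0)) {
    stop("population fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!setequal(names(fr), names(population_mixture$droplet_scale))) {
    stop("`fractions` and `droplet_scale` must share class names",
         call. = FALSE)
  }
  if (any(noise < 0)) stop("noise parameters must be >= 0", call. = FALSE)
  comp_names <- names(components)
  for (compartment in c("nucleus", "cytoplasm", "droplet")) {
    ab <- abundances[[compartment]]
    if (is.null(ab) || is.null(names(ab)) ||
        !all(names(ab) %in% comp_names)) {
      stop("`abundances$", compartment,
           "` must be a named vector over the given components",
           call. = FALSE)
    }
  }
  structure(
    list(image_shape = image_shape, n_channels = as.integer(n_channels),
         wavenumber_range = as.numeric(wavenumber_range),
         n_cells = as.integer(n_cells),
         cell_radius_range = as.numeric(cell_radius_range),
         nucleus_radius_fraction = nucleus_radius_fraction,
         droplets_per_cell = droplets_per_cell,
         droplet_radius_range = as.numeric(droplet_radius_range),
         components = components, abundances = abundances,
         population_mixture = population_mixture,
         noise = stats::setNames(as.numeric(noise),
                                 c("shot_scale", "gaussian_sd")),
         pixel_size = pixel_size, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# disc pixel coordinates around (r0, c0), clipped to the image
.disc_pixels <- function(r0, c0, radius, shape) {
  rr <- max(1L, floor(r0 - radius)):min(shape[1], ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(shape[2], ceiling(c0 + radius))
  grid <- expand.grid(row = rr, col = cc)
  keep <- (grid$row - r0)^2 + (grid$col - c0)^2 <= radius^2
  grid[keep, , drop = FALSE]
}

#' Render a hyperspectral cell phantom with ground truth
#'
#' Places non-overlapping disc cells (bounded rejection sampling), draws a
#' lipid-poor/lipid-rich class per cell, renders each pixel as the linear
#' mixture of component spectra for its compartment (droplet abundances
#' scaled by the cell's class), applies signal-dependent plus additive
#' Gaussian noise, and returns both the stack and a complete ground-truth
#' record: label images and a per-cell truth table. A radial intensity
#' taper is applied to the cytoplasm (total intensity only, so pixel
#' spectral shape — and hence phasor position — is unchanged).
#'
#' @param spec A [phantom_spec()].
#' @return List with `stack` ([hyper_stack()]) and `truth`: a list with
#'   `nuclei_labels`, `cell_labels`, `droplet_labels` (integer matrices, 0
#'   = background), `droplet_to_cell`, and `cells` (per-cell table with
#'   class, droplet count/area, true integrated droplet signal and class
#'   scale).
#' @export
generate_cell_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$image_shape
  axis <- seq(spec$wavenumber_range[1], spec$wavenumber_range[2],
              length.out = spec$n_channels)
  spectra <- lapply(spec$components, make_component_spectrum, axis = axis)

  mix_spectrum <- function(ab) {
    out <- numeric(spec$n_channels)
    for (nm in names(ab)) out <- out + ab[[nm]] * spectra[[nm]]
    out
  }

  nuclei_labels <- matrix(0L, shape[1], shape[2])
  cell_labels <- matrix(0L, shape[1], shape[2])
  droplet_labels <- matrix(0L, shape[1], shape[2])
  # per-pixel compartment code: 0 bg, 1 nucleus, 2 cytoplasm, 3 droplet
  compartment <- matrix(0L, shape[1], shape[2])
  texture <- matrix(1, shape[1], shape[2])

  n_cells <- spec$n_cells
  centers <- matrix(0, n_cells, 2)
  radii <- numeric(n_cells)
  if (n_cells > 0L) {
    rmax <- spec$cell_radius_range[2]
    if (2 * rmax + 2 > min(shape)) {
      stop("packing error: cell_radius_range too large for image_shape",
           call. = FALSE)
    }
    placed <- 0L
    attempts <- 0L
    max_attempts <- 400L * n_cells
    while (placed < n_cells && attempts < max_attempts) {
      attempts <- attempts + 1L
      r <- stats::runif(1, spec$cell_radius_range[1],
                        spec$cell_radius_range[2])
      cy <- stats::runif(1, r + 1, shape[1] - r)
      cx <- stats::runif(1, r + 1, shape[2] - r)
      ok <- TRUE
      if (placed > 0L) {
        dd <- sqrt((centers[seq_len(placed), 1] - cy)^2 +
                   (centers[seq_len(placed), 2] - cx)^2)
        ok <- all(dd > radii[seq_len(placed)] + r + 1)
      }
      if (ok) {
        placed <- placed + 1L
        centers[placed, ] <- c(cy, cx)
        radii[placed] <- r
      }
    }
    if (placed < n_cells) {
      stop(sprintf(
        "packing error: placed %d of %d cells; reduce n_cells or cell_radius_range",
        placed, n_cells), call. = FALSE)
    }
  }

  classes <- character(n_cells)
  class_names <- names(spec$population_mixture$fractions)
  if (n_cells > 0L) {
    classes <- sample(class_names, n_cells, replace = TRUE,
                      prob = spec$population_mixture$fractions)
  }

  droplet_rows <- list()
  droplet_id <- 0L
  cell_truth <- vector("list", n_cells)

  for (i in seq_len(n_cells)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]; r <- radii[i]
    px <- .disc_pixels(cy, cx, r, shape)
    ij <- cbind(px$row, px$col)
    cell_labels[ij] <- i
    compartment[ij] <- 2L
    d <- sqrt((px$row - cy)^2 + (px$col - cx)^2)
    texture[ij] <- 1 - 0.25 * (d / r)^2
    rn <- spec$nucleus_radius_fraction * r
    npx <- .disc_pixels(cy, cx, rn, shape)
    nij <- cbind(npx$row, npx$col)
    nuclei_labels[nij] <- i
    compartment[nij] <- 1L
    texture[nij] <- 1

    k_dr <- stats::rpois(1, spec$droplets_per_cell)
    placed_dr <- 0L
    dr_centers <- matrix(0, 0, 3) # row, col, radius
    tries <- 0L
    while (placed_dr < k_dr && tries < 200L * max(1L, k_dr)) {
      tries <- tries + 1L
      dr <- stats::runif(1, spec$droplet_radius_range[1],
                         spec$droplet_radius_range[2])
      lo <- rn + dr + 0.5
      hi <- r - dr - 0.5
      if (hi <= lo) next # this radius draw does not fit; try another
      rad <- stats::runif(1, lo, hi)
      ang <- stats::runif(1, 0, 2 * pi)
      dy <- cy + rad * sin(ang); dx <- cx + rad * cos(ang)
      clash <- FALSE
      if (placed_dr > 0L) {
        dd <- sqrt((dr_centers[, 1] - dy)^2 + (dr_centers[, 2] - dx)^2)
        clash <- any(dd < dr_centers[, 3] + dr + 1.5)
      }
      if (!clash) {
        placed_dr <- placed_dr + 1L
        dr_centers <- rbind(dr_centers, c(dy, dx, dr))
      }
    }
    for (j in seq_len(placed_dr)) {
      droplet_id <- droplet_id + 1L
      dpx <- .disc_pixels(dr_centers[j, 1], dr_centers[j, 2],
                          dr_centers[j, 3], shape)
      dij <- cbind(dpx$row, dpx$col)
      droplet_labels[dij] <- droplet_id
      compartment[dij] <- 3L
      droplet_rows[[droplet_id]] <- data.frame(
        droplet_id = droplet_id, cell_id = i,
        area_px = nrow(dpx),
        centroid_row = mean(dpx$row), centroid_col = mean(dpx$col))
    }
    cell_truth[[i]] <- data.frame(
      cell_id = i, class = classes[i],
      center_row = cy, center_col = cx, radius = r,
      droplet_count = placed_dr)
  }

  # render noise-free signal
  data <- array(0, dim = c(spec$n_channels, shape[1], shape[2]))
  spec_nuc <- mix_spectrum(spec$abundances$nucleus)
  spec_cyt <- mix_spectrum(spec$abundances$cytoplasm)
  scales <- spec$population_mixture$droplet_scale
  for (k in seq_len(spec$n_channels)) {
    plane <- matrix(0, shape[1], shape[2])
    plane[compartment == 1L] <- spec_nuc[k]
    plane[compartment == 2L] <- spec_cyt[k]
    data[k, , ] <- plane * texture
  }
  spec_dro <- mix_spectrum(spec$abundances$droplet)
  dro_mask <- compartment == 3L
  if (any(dro_mask)) {
    cell_of_droplet_px <- cell_labels[dro_mask]
    px_scale <- scales[classes[cell_of_droplet_px]]
    for (k in seq_len(spec$n_channels)) {
      plane <- data[k, , ]
      plane[dro_mask] <- spec_dro[k] * px_scale
      data[k, , ] <- plane
    }
  }

  # per-cell true integrated droplet signal (noise-free DC over droplet px)
  dc <- apply(data, c(2, 3), sum)
  cells <- if (n_cells > 0L) do.call(rbind, cell_truth) else
    data.frame(cell_id = integer(0), class = character(0),
               center_row = numeric(0), center_col = numeric(0),
               radius = numeric(0), droplet_count = integer(0))
  cells$droplet_area_px <- rep(0L, nrow(cells))
  cells$integrated_droplet_signal <- rep(0, nrow(cells))
  cells$droplet_scale <- if (n_cells > 0L) unname(scales[classes]) else numeric(0)
  if (droplet_id > 0L) {
    for (i in seq_len(n_cells)) {
      m <- dro_mask & cell_labels == i
      cells$droplet_area_px[i] <- sum(m)
      cells$integrated_droplet_signal[i] <- sum(dc[m])
    }
  }

  # noise: sd = shot_scale * sqrt(signal) + additive gaussian_sd
  if (spec$noise[["shot_scale"]] > 0 || spec$noise[["gaussian_sd"]] > 0) {
    sd_arr <- spec$noise[["shot_scale"]] * sqrt(pmax(data, 0))
    data <- data + stats::rnorm(length(data), sd = sd_arr) +
      stats::rnorm(length(data), sd = spec$noise[["gaussian_sd"]])
    data[data < 0] <- 0
  }

  droplet_to_cell <- if (droplet_id > 0L) do.call(rbind, droplet_rows) else
    data.frame(droplet_id = integer(0), cell_id = integer(0),
               area_px = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0))

  stack <- hyper_stack(data, axis, pixel_size = spec$pixel_size,
                       metadata = list(seed = spec$seed,
                                       generator = "generate_cell_phantom"))
  truth <- list(nuclei_labels = nuclei_labels, cell_labels = cell_labels,
                droplet_labels = droplet_labels,
                droplet_to_cell = droplet_to_cell, cells = cells,
                compartment = compartment,
                component_spectra = spectra)
  list(stack = stack, truth = truth)
}
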