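#' Define a spectral component
#'
#' A spectral component is a named sum of Gaussian Raman bands plus a
#' constant baseline, used both to render synthetic hyperspectral phantoms
#' and as a reference spectrum for unmixing and phasor anchoring.
#'
#' @param name Text label, e.g. `"CH_lipid"`, `"CD_glucose"`, `"CC_odya"`.
#' @param peaks A data frame (or matrix) with columns `center`, `width`,
#'   `amplitude`: band centre and Gaussian width in cm^-1, amplitude in
#'   arbitrary units. May have zero rows.
#' @param baseline Constant non-negative offset added at every channel.
#' @return An object of class `spectral_component`.
#' @examples
#' comp <- spectral_component("CC_odya",
#'   data.frame(center = 2100, width = 20, amplitude = 5))
#' axis <- seq(2050, 2350, length.out = 50)
#' spec <- make_component_spectrum(comp, axis)
#' @export
spectral_component <- function(name, peaks = NULL, baseline = 0) {
  if (is.null(peaks)) {
    peaks <- data.frame(center = numeric(0), width = numeric(0),
                        amplitude = numeric(0))
  }
  peaks <- as.data.frame(peaks)
  required <- c("center", "width", "amplitude")
  if (!all(required %in% names(peaks))) {
    stop("`peaks` must have columns center, width, amplitude", call. = FALSE)
  }
  if (nrow(peaks) > 0L) {
    if (any(!is.finite(as.matrix(peaks[required])))) {
      stop("peak parameters must be finite", call. = FALSE)
    }
    if (any(peaks$width <= 0)) stop("all peak widths must be > 0", call. = FALSE)
    if (any(peaks$amplitude < 0)) stop("all peak amplitudes must be >= 0", call. = FALSE)
  }
  if (!is.finite(baseline) || baseline < 0) {
    stop("`baseline` must be a non-negative number", call. = FALSE)
  }
  structure(
    list(name = as.character(name), peaks = peaks[required],
         baseline = baseline),
    class = "spectral_component"
  )
}

#' @export
print.spectral_component <- function(x, ...) {
  cat("<spectral_component>", x$name, "-", nrow(x$peaks), "band(s), baseline",
      x$baseline, "\n")
  invisible(x)
}

#' Evaluate a component spectrum on a wavenumber axis
#'
#' The spectrum at wavenumber nu is
#' `baseline + sum_peaks amplitude * exp(-(nu - center)^2 / (2 width^2))`.
#'
#' @param component A [spectral_component()].
#' @param axis Strictly increasing vector of wavenumbers (cm^-1).
#' @return Numeric vector of intensities, one per axis element; always
#'   non-negative.
#' @export
make_component_spectrum <- function(component, axis) {
  stopifnot(inherits(component, "spectral_component"))
  axis <- as.numeric(axis)
  if (length(axis) < 1L || any(!is.finite(axis))) {
    stop("`axis` must be a finite numeric vector", call. = FALSE)
  }
  if (length(axis) > 1L && any(diff(axis) <= 0)) {
    stop("invalid axis: wavenumbers must be strictly increasing", call. = FALSE)
  }
  out <- rep(component$baseline, length(axis))
  pk <- component$peaks
  for (i in seq_len(nrow(pk))) {
    out <- out + pk$amplitude[i] *
      exp(-(axis - pk$center[i])^2 / (2 * pk$width[i]^2))
  }
  out
}

#' Stock component spectra for the C-H and C-D/C-C windows
#'
#' Convenience set of components used by the phantom generator: a
#' protein-like CH3 band (2930 cm^-1, nuclei and cytoplasm), a lipid CH2
#' band (2850 cm^-1, lipid droplets), a broad C-D band for glucose-d7
#' derived macromolecules (~2150 cm^-1) and the sharp alkyne C-C band of
#' ODYA (~2100 cm^-1).
#'
#' @return Named list of [spectral_component()] objects.
#' @export
default_components <- function() {
  list(
    CH_protein = spectral_component(
      "CH_protein",
      data.frame(center = 2930, width = 35, amplitude = 1)),
    CH_lipid = spectral_component(
      "CH_lipid",
      data.frame(center = c(2850, 2895), width = c(25, 40),
                 amplitude = c(1, 0.35))),
    CD_glucose = spectral_component(
      "CD_glucose",
      data.frame(center = 2150, width = 60, amplitude = 1)),
    CC_odya = spectral_component(
      "CC_odya",
      data.frame(center = 2100, width = 15, amplitude = 1))
  )
}
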