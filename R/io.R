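#' Construct a hyperspectral stack
#'
#' The core imaging container: a 3-D intensity cube with the channel axis
#' first (`data[k, row, col]`), a calibrated wavenumber per channel, and
#' the pixel size in micrometres. Coordinates are row-major with origin at
#' the top-left; channel index k runs over the acquired Raman shifts.
#'
#' @param data Numeric 3-D array `(channel, row, col)` of non-negative
#'   intensities.
#' @param wavenumbers Strictly monotonic vector of Raman shifts (cm^-1),
#'   one per channel.
#' @param pixel_size Pixel size in um/pixel.
#' @param metadata Free-form named list.
#' @return Object of class `hyper_stack`.
#' @export
hyper_stack <- function(data, wavenumbers, pixel_size = 1,
                        metadata = list()) {
  data <- unclass(data)
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array (channel, row, col)", call. = FALSE)
  }
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != dim(data)[1]) {
    stop("length(wavenumbers) must equal the number of channels",
         call. = FALSE)
  }
  if (length(wavenumbers) > 1L) {
    d <- diff(wavenumbers)
    if (!(all(d > 0) || all(d < 0))) {
      stop("`wavenumbers` must be strictly monotonic", call. = FALSE)
    }
  }
  if (any(dim(data)[2:3] < 1L)) {
    stop("spatial dimensions must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("`data` contains non-finite values", call. = FALSE)
  }
  structure(
    list(data = data, wavenumbers = wavenumbers,
         pixel_size = as.numeric(pixel_size), metadata = metadata),
    class = "hyper_stack"
  )
}

#' @export
print.hyper_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hyper_stack> %d channels x %d x %d px, %g-%g cm^-1, %g um/px\n",
    d[1], d[2], d[3], min(x$wavenumbers), max(x$wavenumbers),
    x$pixel_size))
  invisible(x)
}

#' @export
dim.hyper_stack <- function(x) dim(x$data)

#' Write a hyperspectral stack to multi-page TIFF plus JSON sidecar
#'
#' One 32-bit TIFF page per wavenumber. The TIFF layer stores 32-bit
#' fixed-point values in \[0, 1\], so intensities are divided by a
#' power-of-two `scale` (recorded in the sidecar) on write and multiplied
#' back on read; the round trip is exact to 2^-31 of full scale. The
#' sidecar (schema `srsmi-stack/1`) records wavenumbers, pixel size, the
#' scale and free-form metadata.
#'
#' @param stack A [hyper_stack()].
#' @param path Output TIFF path.
#' @param sidecar_path JSON sidecar path; defaults to `paste0(path, ".json")`.
#' @return Invisibly, a list with the paths written.
#' @export
write_stack <- function(stack, path, sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(stack, "hyper_stack"))
  mx <- max(stack$data)
  scale <- if (mx <= 0) 1 else 2^ceiling(log2(mx))
  pages <- lapply(seq_len(dim(stack$data)[1]),
                  function(k) stack$data[k, , , drop = TRUE] / scale)
  # single-row/col pages drop to vectors; keep them matrices
  pages <- lapply(pages, function(p) {
    if (is.null(dim(p))) matrix(p, dim(stack$data)[2], dim(stack$data)[3]) else p
  })
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("could not write TIFF to '", path, "': ",
         attr(ok, "condition")$message, call. = FALSE)
  }
  sidecar <- list(
    schema = "srsmi-stack/1",
    wavenumbers = stack$wavenumbers,
    pixel_size_um = stack$pixel_size,
    scale = scale,
    metadata = stack$metadata
  )
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(list(tiff = path, sidecar = sidecar_path))
}

#' Read a hyperspectral stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @param sidecar_path JSON sidecar path holding the wavenumber
#'   calibration; reading refuses to guess when it is absent or does not
#'   match the page count.
#' @return A [hyper_stack()].
#' @export
read_stack <- function(path, sidecar_path = paste0(path, ".json")) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  if (!file.exists(sidecar_path)) {
    stop("calibration sidecar not found: '", sidecar_path,
         "' (wavenumber calibration is required)", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  wn <- as.numeric(side$wavenumbers)
  if (length(wn) != length(pages)) {
    stop(sprintf(
      "calibration error: sidecar lists %d wavenumbers but TIFF has %d pages",
      length(wn), length(pages)), call. = FALSE)
  }
  scale <- if (is.null(side$scale)) 1 else as.numeric(side$scale)
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  data <- array(0, dim = c(length(pages), nr, nc))
  for (k in seq_along(pages)) data[k, , ] <- pages[[k]] * scale
  n_nan <- sum(!is.finite(data))
  md <- if (is.null(side$metadata)) list() else as.list(side$metadata)
  if (n_nan > 0L) {
    data[!is.finite(data)] <- 0
    md$n_nonfinite_flagged <- n_nan
    warning(n_nan, " non-finite pixel values flagged and set to 0")
  }
  hyper_stack(data, wn,
              pixel_size = if (is.null(side$pixel_size_um)) 1 else
                as.numeric(side$pixel_size_um),
              metadata = md)
}

#' Describe a tile montage
#'
#' @param grid `(tiles_y, tiles_x)` tile counts.
#' @param tile_shape `(rows, cols)` pixels per tile.
#' @param overlap_fraction Fractional overlap between adjacent tiles, in
#'   \[0, 1); non-integer overlap pixel counts are floored.
#' @param blend `"feather"` (linear ramp across the overlap) or
#'   `"first"` (earlier tile wins).
#' @return Object of class `montage_layout`.
#' @export
montage_layout <- function(grid, tile_shape, overlap_fraction = 0,
                           blend = c("feather", "first")) {
  grid <- as.integer(grid)
  tile_shape <- as.integer(tile_shape)
  stopifnot(length(grid) == 2L, length(tile_shape) == 2L)
  if (any(grid < 1L)) stop("grid counts must be >= 1", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("`overlap_fraction` must be in [0, 1)", call. = FALSE)
  }
  blend <- match.arg(blend)
  structure(list(grid = grid, tile_shape = tile_shape,
                 overlap_fraction = overlap_fraction, blend = blend),
            class = "montage_layout")
}

#' Stitch hyperspectral tiles into a large-area montage
#'
#' Tiles are placed from stage positions implied by the layout (row-major
#' order: left to right, then top to bottom), the convention of a motorized
#' stage acquiring a grid such as 5 x 5 tiles of 400 x 400 pixels.
#' Overlapping strips are blended per the layout policy; non-overlap pixels
#' are copied unchanged.
#'
#' @param tiles List of [hyper_stack()] tiles in row-major order, all
#'   sharing wavenumber axis and shape equal to `layout$tile_shape`.
#' @param layout A [montage_layout()].
#' @return A [hyper_stack()] of spatial size
#'   `tile_shape * grid - overlap_px * (grid - 1)` per axis, where
#'   `overlap_px = floor(overlap_fraction * tile_shape)`.
#' @export
stitch_montage <- function(tiles, layout) {
  stopifnot(inherits(layout, "montage_layout"))
  ntiles <- prod(layout$grid)
  if (length(tiles) != ntiles) {
    stop(sprintf("layout needs %d tiles, got %d", ntiles, length(tiles)),
         call. = FALSE)
  }
  wn <- tiles[[1]]$wavenumbers
  tshape <- dim(tiles[[1]]$data)[2:3]
  for (tl in tiles) {
    if (!inherits(tl, "hyper_stack") ||
        !isTRUE(all.equal(tl$wavenumbers, wn)) ||
        !identical(dim(tl$data)[2:3], tshape)) {
      stop("incompatible tiles: all tiles must share wavenumber axis and shape",
           call. = FALSE)
    }
  }
  if (!identical(as.integer(tshape), layout$tile_shape)) {
    stop("tile shape does not match layout$tile_shape", call. = FALSE)
  }
  ov <- as.integer(floor(layout$overlap_fraction * layout$tile_shape))
  step <- layout$tile_shape - ov
  out_shape <- layout$tile_shape + step * (layout$grid - 1L)
  nchan <- length(wn)
  num <- array(0, dim = c(nchan, out_shape[1], out_shape[2]))
  den <- matrix(0, out_shape[1], out_shape[2])

  ramp <- function(n, ov_lo, ov_hi) {
    w <- rep(1, n)
    if (ov_lo > 0L) w[seq_len(ov_lo)] <- seq_len(ov_lo) / (ov_lo + 1)
    if (ov_hi > 0L) w[n - seq_len(ov_hi) + 1L] <- seq_len(ov_hi) / (ov_hi + 1)
    w
  }

  idx <- 1L
  for (ty in seq_len(layout$grid[1])) {
    for (tx in seq_len(layout$grid[2])) {
      r0 <- (ty - 1L) * step[1]
      c0 <- (tx - 1L) * step[2]
      rows <- r0 + seq_len(layout$tile_shape[1])
      cols <- c0 + seq_len(layout$tile_shape[2])
      if (layout$blend == "feather") {
        wr <- ramp(layout$tile_shape[1],
                   if (ty > 1L) ov[1] else 0L,
                   if (ty < layout$grid[1]) ov[1] else 0L)
        wc <- ramp(layout$tile_shape[2],
                   if (tx > 1L) ov[2] else 0L,
                   if (tx < layout$grid[2]) ov[2] else 0L)
        w <- outer(wr, wc)
      } else {
        w <- matrix(1, layout$tile_shape[1], layout$tile_shape[2])
        w[den[rows, cols] > 0] <- 0
      }
      td <- tiles[[idx]]$data
      for (k in seq_len(nchan)) {
        num[k, rows, cols] <- num[k, rows, cols] + td[k, , ] * w
      }
      den[rows, cols] <- den[rows, cols] + w
      idx <- idx + 1L
    }
  }
  den[den == 0] <- 1
  for (k in seq_len(nchan)) num[k, , ] <- num[k, , ] / den
  hyper_stack(num, wn, pixel_size = tiles[[1]]$pixel_size,
              metadata = list(montage_grid = layout$grid,
                              overlap_px = ov, blend = layout$blend))
}
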