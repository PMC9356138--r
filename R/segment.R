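# EBImage works on (x, y) Images; all public functions here take and return
# plain (row, col) matrices and convert internally via t().

.as_ebi <- function(m) EBImage::Image(t(m))
.from_ebi <- function(img) t(EBImage::imageData(img))

.otsu01 <- function(img_matrix, clip = FALSE) {
  if (clip) {
    # clip a small very-bright class (e.g. lipid droplets) so it cannot
    # drag the threshold above the main foreground mode
    pos <- img_matrix[img_matrix > 0]
    if (length(pos) > 0L) {
      img_matrix <- pmin(img_matrix, 2 * stats::median(pos))
    }
  }
  mx <- max(img_matrix)
  if (mx <= 0) return(Inf) # nothing above background
  EBImage::otsu(EBImage::Image(t(img_matrix / mx)), range = c(0, 1)) * mx
}

# relabel positive integer image to consecutive 1..n (0 preserved)
.relabel <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(list(labels = lab, map = integer(0)))
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  list(labels = lab, map = ids)
}

#' Segment nuclei from a nuclei component image
#'
#' Thresholds the nuclei map (Otsu by default), labels connected
#' components, splits touching nuclei by a distance-transform watershed,
#' and filters by area.
#'
#' @param nuclei_image Non-negative intensity matrix (the phasor-mapped
#'   nuclei component).
#' @param min_area,max_area Area filter in pixels; `min_area < max_area`
#'   required.
#' @param threshold Intensity threshold; `NULL` uses Otsu's method.
#' @return Integer label matrix (0 = background, labels consecutive).
#' @export
segment_nuclei <- function(nuclei_image, min_area = 20, max_area = Inf,
                           threshold = NULL) {
  if (any(nuclei_image < 0)) stop("image must be non-negative", call. = FALSE)
  if (min_area >= max_area) {
    stop("config error: min_area must be < max_area", call. = FALSE)
  }
  if (is.null(threshold)) threshold <- .otsu01(nuclei_image)
  mask <- nuclei_image > threshold
  if (!any(mask)) return(matrix(0L, nrow(nuclei_image), ncol(nuclei_image)))
  ebi_mask <- .as_ebi(mask * 1)
  dm <- EBImage::distmap(ebi_mask)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labm <- .from_ebi(lab)
  # area filter
  tab <- table(labm[labm > 0])
  bad <- as.integer(names(tab))[tab < min_area | tab > max_area]
  labm[labm %in% bad] <- 0L
  .relabel(labm)$labels
}

#' Outline individual cells by nucleus-seeded region growing
#'
#' Grows each nucleus seed through the whole-cell foreground using
#' Voronoi-based region propagation on the intensity image (the same
#' seeded secondary-object algorithm used by CellProfiler's cell
#' outlining). The resulting cells partition the foreground and cell `i`
#' contains nucleus `i`.
#'
#' @param whole_cell_image Intensity matrix of the whole-cell signal
#'   (e.g. channel-summed stack).
#' @param nuclei_labels Integer label matrix of nuclei seeds.
#' @param threshold Foreground threshold; `NULL` uses Otsu's method.
#' @param lambda Regularization of [EBImage::propagate()] trading
#'   intensity gradients against Euclidean distance.
#' @return Integer cell label matrix; labels equal their seed nucleus
#'   label. Nuclei falling outside the foreground are kept (grown from the
#'   seed) with a warning.
#' @export
outline_cells <- function(whole_cell_image, nuclei_labels, threshold = NULL,
                          lambda = 1e-4) {
  stopifnot(identical(dim(whole_cell_image), dim(nuclei_labels)))
  if (max(nuclei_labels) == 0L) {
    return(matrix(0L, nrow(whole_cell_image), ncol(whole_cell_image)))
  }
  if (is.null(threshold)) threshold <- .otsu01(whole_cell_image, clip = TRUE)
  fg <- whole_cell_image > threshold
  outside <- nuclei_labels > 0L & !fg
  if (any(outside)) {
    warning(sum(outside), " nucleus pixel(s) outside foreground; ",
            "cells grown from seeds anyway")
    fg <- fg | nuclei_labels > 0L
  }
  cells <- EBImage::propagate(.as_ebi(whole_cell_image),
                              seeds = .as_ebi(nuclei_labels),
                              mask = .as_ebi(fg * 1), lambda = lambda)
  m <- .from_ebi(cells)
  storage.mode(m) <- "integer"
  m
}

#' Detect lipid-droplet particles and assign them to cells
#'
#' Thresholds the lipid component image, splits merged droplets with a
#' distance-transform watershed, filters by minimum diameter, and assigns
#' each droplet to the cell containing its centroid (droplets whose
#' centroid falls on background are dropped and counted).
#'
#' @param lipid_image Intensity matrix of the lipid component.
#' @param cell_labels Integer cell label matrix on the same grid.
#' @param min_diameter Minimum droplet diameter in pixels (default 3:
#'   lipid droplets are diffraction-limited puncta; smaller components are
#'   noise).
#' @param intensity_floor Pixels strictly above this value are droplet
#'   candidates. The default 0 suits phasor component maps, which are
#'   exactly zero outside their cluster; raw intensity images need an
#'   explicit floor.
#' @return List with `droplet_labels` (integer matrix), `droplet_to_cell`
#'   (data frame: droplet_id, cell_id, area_px, centroid_row,
#'   centroid_col) and `n_dropped` (background-centroid droplets).
#' @export
detect_droplets <- function(lipid_image, cell_labels, min_diameter = 3,
                            intensity_floor = 0) {
  if (!identical(dim(lipid_image), dim(cell_labels))) {
    stop("lipid image and cell labels must share the same grid",
         call. = FALSE)
  }
  empty <- list(
    droplet_labels = matrix(0L, nrow(lipid_image), ncol(lipid_image)),
    droplet_to_cell = data.frame(droplet_id = integer(0),
                                 cell_id = integer(0), area_px = integer(0),
                                 centroid_row = numeric(0),
                                 centroid_col = numeric(0)),
    n_dropped = 0L)
  mask <- lipid_image > intensity_floor
  if (!any(mask)) return(empty)
  dm <- EBImage::distmap(.as_ebi(mask * 1))
  lab <- .from_ebi(EBImage::watershed(dm, tolerance = 1, ext = 1))
  min_area <- pi * (min_diameter / 2)^2
  tab <- table(lab[lab > 0])
  lab[lab %in% as.integer(names(tab))[tab < min_area]] <- 0L
  rl <- .relabel(lab)
  lab <- rl$labels
  n <- length(rl$map)
  if (n == 0L) return(empty)

  rows <- row(lab); cols <- col(lab)
  cr <- vapply(seq_len(n), function(i) mean(rows[lab == i]), 0)
  cc <- vapply(seq_len(n), function(i) mean(cols[lab == i]), 0)
  area <- as.integer(table(factor(lab[lab > 0], levels = seq_len(n))))
  cell <- cell_labels[cbind(pmin(pmax(round(cr), 1), nrow(lab)),
                            pmin(pmax(round(cc), 1), ncol(lab)))]
  keep <- cell > 0L
  n_dropped <- sum(!keep)
  lab[lab %in% which(!keep)] <- 0L
  rl2 <- .relabel(lab)
  kept <- which(keep)
  list(
    droplet_labels = rl2$labels,
    droplet_to_cell = data.frame(
      droplet_id = seq_along(kept), cell_id = as.integer(cell[kept]),
      area_px = area[kept], centroid_row = cr[kept],
      centroid_col = cc[kept]),
    n_dropped = as.integer(n_dropped))
}

#' Cells touching the image border
#'
#' @param cell_labels Integer cell label matrix.
#' @return Integer vector of labels with at least one border pixel.
#' @export
edge_cells <- function(cell_labels) {
  border <- c(cell_labels[1, ], cell_labels[nrow(cell_labels), ],
              cell_labels[, 1], cell_labels[, ncol(cell_labels)])
  sort(unique(border[border > 0L]))
}
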