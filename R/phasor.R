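#' Spectral phasor transform of a hyperspectral stack
#'
#' Embeds each pixel's spectrum in the phasor plane via its first-harmonic
#' discrete Fourier coefficients normalized by total intensity:
#' `g = sum_k I_k cos(2 pi h k / N) / sum_k I_k` and
#' `s = sum_k I_k sin(2 pi h k / N) / sum_k I_k`, `k = 0..N-1`. Pixels
#' whose total (DC) intensity falls at or below `dc_floor` are marked
#' invalid and excluded from clustering. For non-negative spectra all
#' valid phasors lie in the unit disc, and the transform is invariant to
#' global intensity scaling — the geometry that makes spectrally similar
#' pixels cluster regardless of brightness.
#'
#' @param stack A [hyper_stack()] with at least 2 channels.
#' @param harmonic Positive integer harmonic (default 1, the standard
#'   phasor convention; higher harmonics are exposed for completeness).
#' @param dc_floor Validity threshold on total intensity. `NULL` (default)
#'   estimates it as `median + 5 * mad` of the DC values in the four
#'   8 x 8 image corners, a robust background estimate.
#' @return Object of class `phasor_field`: matrices `g`, `s`, `dc`,
#'   logical `valid`, plus `n_channels` and `harmonic`.
#' @export
phasor_transform <- function(stack, harmonic = 1L, dc_floor = NULL) {
  stopifnot(inherits(stack, "hyper_stack"))
  N <- dim(stack$data)[1]
  if (N < 2L) stop("phasor transform needs >= 2 channels", call. = FALSE)
  harmonic <- as.integer(harmonic)
  if (is.na(harmonic) || harmonic < 1L) {
    stop("`harmonic` must be a positive integer", call. = FALSE)
  }
  shape <- dim(stack$data)[2:3]
  mat <- matrix(stack$data, nrow = N) # N x (rows*cols), pixels column-major
  k <- 0:(N - 1)
  ck <- cos(2 * pi * harmonic * k / N)
  sk <- sin(2 * pi * harmonic * k / N)
  dc <- colSums(mat)
  g <- as.vector(crossprod(ck, mat))
  s <- as.vector(crossprod(sk, mat))
  if (is.null(dc_floor)) dc_floor <- estimate_dc_floor(matrix(dc, shape[1], shape[2]))
  valid <- dc > dc_floor & is.finite(dc)
  g <- ifelse(valid, g / dc, NA_real_)
  s <- ifelse(valid, s / dc, NA_real_)
  structure(
    list(g = matrix(g, shape[1], shape[2]),
         s = matrix(s, shape[1], shape[2]),
         dc = matrix(dc, shape[1], shape[2]),
         valid = matrix(valid, shape[1], shape[2]),
         n_channels = N, harmonic = harmonic, dc_floor = dc_floor),
    class = "phasor_field"
  )
}

#' Robust background floor from image corners
#'
#' @param dc_image Matrix of per-pixel total intensity.
#' @param corner Corner patch side length in pixels.
#' @param k Multiplier on the MAD.
#' @return `median + k * mad` over the corner pixels.
#' @export
estimate_dc_floor <- function(dc_image, corner = 8L, k = 5) {
  nr <- nrow(dc_image); nc <- ncol(dc_image)
  a <- min(corner, nr); b <- min(corner, nc)
  vals <- c(dc_image[1:a, 1:b], dc_image[1:a, (nc - b + 1):nc],
            dc_image[(nr - a + 1):nr, 1:b],
            dc_image[(nr - a + 1):nr, (nc - b + 1):nc])
  stats::median(vals) + k * stats::mad(vals)
}

# phasor coordinates of a single spectrum (used to anchor cluster names)
.spectrum_phasor <- function(spectrum, harmonic = 1L) {
  N <- length(spectrum)
  k <- 0:(N - 1)
  tot <- sum(spectrum)
  c(g = sum(spectrum * cos(2 * pi * harmonic * k / N)) / tot,
    s = sum(spectrum * sin(2 * pi * harmonic * k / N)) / tot)
}

#' Cluster pixels on the phasor plane
#'
#' Groups valid pixels by their (g, s) coordinates so that pixels of
#' similar spectra (chemical content) form clusters that can be mapped
#' back to component images. Methods: `"gmm"` (Gaussian mixture with a
#' regularizing prior, the default), `"kmeans"`, or `"polygon"` gating
#' (the programmatic equivalent of drawing regions on an interactive
#' phasor plot). Cluster ids are relabelled in descending order of total
#' DC intensity; id 0 means unassigned/background.
#'
#' @param field A [phasor_field()].
#' @param method `"gmm"`, `"kmeans"` or `"polygon"`.
#' @param k Number of clusters (parametric methods).
#' @param gates For `"polygon"`: named list of vertex matrices (columns
#'   g, s); gates must not self-intersect. Pixels in no gate stay 0.
#' @param seed Integer seed (parametric methods are deterministic given it).
#' @param references Optional named list of reference spectra (on the
#'   stack's axis); cluster ids are mapped to the reference whose phasor
#'   is nearest each centroid (greedy one-to-one).
#' @param component_names Optional character vector naming clusters in
#'   descending-DC order when no references are given.
#' @return Object of class `phasor_clustering`: `method`, `assignments`
#'   (integer matrix), `centroids` or `gates`, `component_map`.
#' @export
cluster_phasor <- function(field, method = c("gmm", "kmeans", "polygon"),
                           k = NULL, gates = NULL, seed = 1,
                           references = NULL, component_names = NULL) {
  stopifnot(inherits(field, "phasor_field"))
  method <- match.arg(method)
  v <- which(field$valid)
  X <- cbind(g = field$g[v], s = field$s[v])
  assignments <- matrix(0L, nrow(field$g), ncol(field$g))

  if (method == "polygon") {
    if (is.null(gates) || length(gates) == 0L) {
      stop("polygon method requires `gates`", call. = FALSE)
    }
    lab <- integer(length(v))
    for (i in seq_along(gates)) {
      gm <- as.matrix(gates[[i]])
      inside <- mgcv::in.out(rbind(gm, gm[1, ]), X)
      lab[inside & lab == 0L] <- i
    }
    assignments[v] <- lab
    centroids <- NULL
  } else {
    if (is.null(k)) stop("`k` is required for parametric methods", call. = FALSE)
    k <- as.integer(k)
    if (length(v) < k) {
      stop("insufficient data: fewer valid pixels than clusters", call. = FALSE)
    }
    set.seed(seed)
    lab <- NULL
    if (method == "gmm") {
      fit <- try(suppressWarnings(
        mclust::Mclust(X, G = k, prior = mclust::priorControl(),
                       verbose = FALSE)), silent = TRUE)
      if (!inherits(fit, "try-error") && !is.null(fit)) {
        lab <- fit$classification
      }
    }
    if (is.null(lab)) { # kmeans, or gmm fallback on degenerate data
      Xj <- unique(X)
      if (nrow(Xj) < k) {
        stop("insufficient data: fewer distinct phasor points than clusters",
             call. = FALSE)
      }
      km <- suppressWarnings(stats::kmeans(X, centers = Xj[
        seq(1, nrow(Xj), length.out = k), , drop = FALSE], iter.max = 100))
      lab <- km$cluster
    }
    assignments[v] <- lab
    centroids <- do.call(rbind, lapply(seq_len(k), function(i) {
      colMeans(X[lab == i, , drop = FALSE])
    }))
  }

  if (method == "polygon") {
    # gate order is the user's semantic order; ids stay gate indices
    n_clusters <- length(gates)
  } else {
    # relabel clusters by descending total DC (stable, deterministic order)
    ids <- seq_len(k)
    tot_dc <- vapply(ids, function(i) sum(field$dc[assignments == i]), 0)
    ord <- ids[order(-tot_dc)]
    remap <- integer(k)
    remap[ord] <- seq_len(k)
    pos <- assignments > 0L
    assignments[pos] <- remap[assignments[pos]]
    centroids <- centroids[ord, , drop = FALSE]
    n_clusters <- k
  }
  component_map <- character(n_clusters)
  if (!is.null(references) && n_clusters > 0L && !is.null(centroids)) {
    ref_ph <- t(vapply(references, .spectrum_phasor, c(g = 0, s = 0),
                       harmonic = field$harmonic))
    # greedy one-to-one: closest (centroid, reference) pairs first
    dists <- as.matrix(stats::dist(rbind(centroids, ref_ph)))
    dists <- dists[seq_len(n_clusters),
                   n_clusters + seq_len(nrow(ref_ph)), drop = FALSE]
    left_c <- seq_len(n_clusters); left_r <- seq_len(nrow(ref_ph))
    while (length(left_c) > 0L && length(left_r) > 0L) {
      sub <- dists[left_c, left_r, drop = FALSE]
      ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      component_map[left_c[ij[1]]] <- names(references)[left_r[ij[2]]]
      left_c <- left_c[-ij[1]]; left_r <- left_r[-ij[2]]
    }
    component_map[component_map == ""] <-
      paste0("cluster", which(component_map == ""))
  } else if (!is.null(component_names)) {
    component_map <- rep_len(component_names, n_clusters)
  } else if (method == "polygon" && !is.null(names(gates))) {
    component_map <- names(gates)
  } else if (n_clusters > 0L) {
    component_map <- paste0("cluster", seq_len(n_clusters))
  }
  if (anyDuplicated(component_map)) {
    stop("component names must be unique", call. = FALSE)
  }
  structure(
    list(method = method, assignments = assignments,
         centroids = centroids, gates = if (method == "polygon") gates,
         component_map = component_map, seed = seed),
    class = "phasor_clustering"
  )
}

#' Map phasor clusters back to component images
#'
#' Reconstructs one image per chemical component: the pixel's total (DC)
#' intensity where the pixel belongs to that component's cluster, 0
#' elsewhere — the step that turns phasor clusters into, e.g., separate
#' nuclei and lipid maps.
#'
#' @param clustering A [cluster_phasor()] result.
#' @param field The [phasor_field()] the clustering was computed on.
#' @param components Component names to map (default: all in the
#'   clustering's component map).
#' @return Named list of intensity matrices.
#' @export
map_clusters_to_images <- function(clustering, field, components = NULL) {
  stopifnot(inherits(clustering, "phasor_clustering"),
            inherits(field, "phasor_field"))
  if (is.null(components)) components <- clustering$component_map
  out <- vector("list", length(components))
  names(out) <- components
  for (nm in components) {
    id <- match(nm, clustering$component_map)
    if (is.na(id)) stop("unknown component name: '", nm, "'", call. = FALSE)
    img <- matrix(0, nrow(field$dc), ncol(field$dc))
    sel <- clustering$assignments == id
    img[sel] <- field$dc[sel]
    out[[nm]] <- img
  }
  out
}

#' Least-squares unmixing of two Raman probes
#'
#' Decomposes each pixel spectrum into non-negative abundances of two
#' reference spectra (e.g. the alkyne C-C band of an ODYA fatty-acid
#' tracer and the C-D band of glucose-d7-derived macromolecules) —
#' the linear-unmixing counterpart of phasor-based two-probe
#' segmentation, with a residual image for QC.
#'
#' @param stack A [hyper_stack()].
#' @param references Named list of two reference spectra on the stack's
#'   axis; must be linearly independent.
#' @param background Constant spectrum (or scalar) subtracted before
#'   unmixing.
#' @return List with one abundance matrix per reference (clipped at 0 by
#'   non-negative least squares) and `residual`, the per-pixel residual
#'   2-norm.
#' @export
unmix_dual_probe <- function(stack, references, background = 0) {
  stopifnot(inherits(stack, "hyper_stack"), length(references) == 2L)
  N <- dim(stack$data)[1]
  A <- cbind(as.numeric(references[[1]]), as.numeric(references[[2]]))
  if (nrow(A) != N) {
    stop("reference spectra must match the stack's channel count",
         call. = FALSE)
  }
  G <- crossprod(A)
  cond <- kappa(G, exact = TRUE)
  if (!is.finite(cond) || cond > 1e10) {
    stop("conditioning error: reference spectra are (near-)collinear",
         call. = FALSE)
  }
  shape <- dim(stack$data)[2:3]
  Y <- matrix(stack$data, nrow = N) - background
  AtY <- crossprod(A, Y) # 2 x P
  Ginv <- solve(G)
  B <- Ginv %*% AtY # unconstrained LS, 2 x P
  a1 <- B[1, ]; a2 <- B[2, ]
  neg <- a1 < 0 | a2 < 0
  if (any(neg)) {
    # 2-variable NNLS: clamp each coefficient to zero in turn, keep best
    b1 <- pmax(AtY[1, neg] / G[1, 1], 0) # a2 = 0
    b2 <- pmax(AtY[2, neg] / G[2, 2], 0) # a1 = 0
    yty <- colSums(Y[, neg, drop = FALSE]^2)
    rss1 <- yty - 2 * b1 * AtY[1, neg] + b1^2 * G[1, 1]
    rss2 <- yty - 2 * b2 * AtY[2, neg] + b2^2 * G[2, 2]
    use1 <- rss1 <= rss2
    a1[neg] <- ifelse(use1, b1, 0)
    a2[neg] <- ifelse(use1, 0, b2)
  }
  fit <- A %*% rbind(a1, a2)
  resid <- sqrt(colSums((Y - fit)^2))
  out <- list(matrix(a1, shape[1], shape[2]),
              matrix(a2, shape[1], shape[2]))
  names(out) <- names(references)
  out$residual <- matrix(resid, shape[1], shape[2])
  out
}
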