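# Small phantoms shared across tests. Phantom geometry is kept modest so the
# whole suite runs in well under a minute per file.

small_phantom <- function(seed = 3, n_cells = 8, noise = c(0, 0), ...) {
  generate_cell_phantom(phantom_spec(
    image_shape = c(160L, 160L), n_cells = n_cells, noise = noise,
    seed = seed, ...))
}

# reference spectra for the default C-H phantom compartments
ch_references <- function(axis) {
  comps <- default_components()
  prot <- make_component_spectrum(comps$CH_protein, axis)
  lip <- make_component_spectrum(comps$CH_lipid, axis)
  list(nuclei = prot, cytoplasm = 0.7 * prot + 0.3 * lip, lipid = lip)
}

# run phasor clustering + mapping on a phantom, returning component images
phantom_component_images <- function(ph, seed = 1) {
  f <- phasor_transform(ph$stack)
  cl <- cluster_phasor(f, method = "gmm", k = 3, seed = seed,
                       references = ch_references(ph$stack$wavenumbers))
  list(field = f, clustering = cl,
       images = map_clusters_to_images(cl, f))
}

# map detected cell labels onto truth cell ids by majority pixel overlap
match_cells_to_truth <- function(detected, truth_labels) {
  ids <- sort(unique(detected[detected > 0L]))
  vapply(ids, function(i) {
    ov <- truth_labels[detected == i]
    ov <- ov[ov > 0L]
    if (length(ov) == 0L) NA_integer_ else
      as.integer(names(which.max(table(ov))))
  }, integer(1))
}

# independent brute-force AUC oracle: concordant-pair fraction with
# half-credit for ties, enumerated over all positive x negative pairs
auc_brute_force <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}
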