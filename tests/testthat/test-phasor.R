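make_stack_from_spectra <- function(spectra_list, wn) {
  # one pixel per spectrum, laid out in a single row
  n <- length(spectra_list)
  data <- array(0, dim = c(length(wn), 1, n))
  for (i in seq_len(n)) data[, 1, i] <- spectra_list[[i]]
  hyper_stack(data, wn)
}

test_that("phasor transform matches the DFT closed form", {
  wn <- seq(2800, 3050, length.out = 50)

  # constant spectrum: full-period cosine/sine sums vanish
  const <- make_stack_from_spectra(list(rep(3, 50)), wn)
  f <- phasor_transform(const, dc_floor = 0)
  expect_equal(f$g[1, 1], 0, tolerance = 1e-12)
  expect_equal(f$s[1, 1], 0, tolerance = 1e-12)

  # delta spectrum at k = 10 of N = 50: phasor on the unit circle
  delta <- rep(0, 50); delta[11] <- 2 # k counts from 0
  fd <- phasor_transform(make_stack_from_spectra(list(delta), wn),
                         dc_floor = 0)
  expect_equal(fd$g[1, 1], cos(2 * pi * 10 / 50), tolerance = 1e-12)
  expect_equal(fd$s[1, 1], sin(2 * pi * 10 / 50), tolerance = 1e-12)
  expect_equal(fd$g[1, 1]^2 + fd$s[1, 1]^2, 1, tolerance = 1e-12)

  # 50/50 mixture of deltas at k = 0 and k = 25: midpoint of (1,0), (-1,0)
  mix <- rep(0, 50); mix[1] <- 1; mix[26] <- 1
  fm <- phasor_transform(make_stack_from_spectra(list(mix), wn),
                         dc_floor = 0)
  expect_equal(fm$g[1, 1], 0, tolerance = 1e-12)
  expect_equal(fm$s[1, 1], 0, tolerance = 1e-12)

  expect_error(phasor_transform(hyper_stack(array(1, c(1, 2, 2)), 2850)),
               ">= 2 channels")
  expect_error(phasor_transform(const, harmonic = 0), "positive integer")
})

test_that("phasors of non-negative spectra stay in the unit disc and mix linearly", {
  set.seed(14)
  wn <- seq(2800, 3050, length.out = 50)
  k <- 0:49
  for (i in 1:25) {
    a <- runif(50, 0, 5)
    b <- runif(50, 0, 5)
    alpha <- runif(1)
    mix <- alpha * a + (1 - alpha) * b
    f <- phasor_transform(make_stack_from_spectra(list(a, b, mix), wn),
                          dc_floor = 0)
    expect_true(all(f$g^2 + f$s^2 <= 1 + 1e-12))
    # DC-weighted segment: phasor(mix) = (wa*pa + wb*pb) / (wa + wb)
    wa <- alpha * sum(a); wb <- (1 - alpha) * sum(b)
    expect_equal(f$g[1, 3], (wa * f$g[1, 1] + wb * f$g[1, 2]) / (wa + wb),
                 tolerance = 1e-10)
    expect_equal(f$s[1, 3], (wa * f$s[1, 1] + wb * f$s[1, 2]) / (wa + wb),
                 tolerance = 1e-10)
    # scale invariance
    fc <- phasor_transform(make_stack_from_spectra(list(7.3 * a), wn),
                           dc_floor = 0)
    expect_equal(fc$g[1, 1], f$g[1, 1], tolerance = 1e-12)
    expect_equal(fc$s[1, 1], f$s[1, 1], tolerance = 1e-12)
  }
})

test_that("clustering a noise-free phantom recovers compartment masks", {
  ph <- small_phantom(seed = 3, noise = c(0, 0))
  out <- phantom_component_images(ph)
  imgs <- out$images
  expect_setequal(names(imgs), c("nuclei", "cytoplasm", "lipid"))
  expect_identical(unname(imgs$lipid > 0),
                   unname(ph$truth$droplet_labels > 0))
  expect_identical(unname(imgs$nuclei > 0),
                   unname(ph$truth$nuclei_labels > 0))
  # component images partition the DC image over valid pixels
  total <- imgs$nuclei + imgs$cytoplasm + imgs$lipid
  expect_equal(total[out$field$valid], out$field$dc[out$field$valid])
  expect_true(all((imgs$nuclei > 0) + (imgs$cytoplasm > 0) +
                    (imgs$lipid > 0) <= 1))
})

test_that("polygon gates assign pixels like an interactive phasor plot", {
  ph <- small_phantom(seed = 3, noise = c(0, 0))
  f <- phasor_transform(ph$stack)
  rng_g <- range(f$g[f$valid]); rng_s <- range(f$s[f$valid])
  all_gate <- cbind(g = c(rng_g[1] - 1, rng_g[2] + 1, rng_g[2] + 1,
                          rng_g[1] - 1),
                    s = c(rng_s[1] - 1, rng_s[1] - 1, rng_s[2] + 1,
                          rng_s[2] + 1))
  cl <- cluster_phasor(f, method = "polygon", gates = list(all = all_gate))
  expect_equal(sum(cl$assignments > 0), sum(f$valid))
  img <- map_clusters_to_images(cl, f)$all
  expect_equal(img[f$valid], f$dc[f$valid]) # single cluster -> DC image

  empty_gate <- cbind(g = c(10, 11, 11, 10), s = c(10, 10, 11, 11))
  cl0 <- cluster_phasor(f, method = "polygon",
                        gates = list(none = empty_gate))
  expect_equal(sum(cl0$assignments > 0), 0)

  expect_error(map_clusters_to_images(cl, f, components = "bogus"),
               "unknown component")
  expect_error(cluster_phasor(f, method = "gmm", k = sum(f$valid) + 1),
               "insufficient")
})

test_that("dual-probe least-squares unmixing recovers abundances", {
  set.seed(1)
  axis <- seq(2050, 2350, length.out = 50)
  comps <- default_components()
  rcc <- make_component_spectrum(comps$CC_odya, axis)
  rcd <- make_component_spectrum(comps$CD_glucose, axis)
  refs <- list(CC = rcc, CD = rcd)

  pure <- make_stack_from_spectra(list(rcc), axis)
  u <- unmix_dual_probe(pure, refs)
  expect_equal(u$CC[1, 1], 1, tolerance = 1e-9)
  expect_equal(u$CD[1, 1], 0, tolerance = 1e-9)
  expect_equal(u$residual[1, 1], 0, tolerance = 1e-9)

  mixed <- make_stack_from_spectra(list(0.3 * rcc + 0.7 * rcd), axis)
  um <- unmix_dual_probe(mixed, refs)
  expect_equal(um$CC[1, 1], 0.3, tolerance = 1e-9)
  expect_equal(um$CD[1, 1], 0.7, tolerance = 1e-9)

  # spectrum orthogonal to both references: zero abundances, full residual
  qr_refs <- qr(cbind(rcc, rcd))
  ortho <- abs(qr.resid(qr_refs, rnorm(50, sd = 1)))
  ortho <- qr.resid(qr_refs, ortho) # orthogonal but possibly negative
  so <- make_stack_from_spectra(list(ortho), axis)
  uo <- unmix_dual_probe(so, refs)
  expect_equal(uo$CC[1, 1], 0, tolerance = 1e-9)
  expect_equal(uo$CD[1, 1], 0, tolerance = 1e-9)
  expect_equal(uo$residual[1, 1], sqrt(sum(ortho^2)), tolerance = 1e-9)

  expect_error(unmix_dual_probe(pure, list(a = rcc, b = 2 * rcc)),
               "collinear")
})

test_that("phasor and unmixing routes agree on pure-abundance pixels", {
  axis <- seq(2050, 2350, length.out = 50)
  comps <- default_components()[c("CC_odya", "CD_glucose")]
  ph <- generate_cell_phantom(phantom_spec(
    image_shape = c(96L, 96L), n_cells = 4L,
    wavenumber_range = c(2050, 2350), components = comps,
    abundances = list(nucleus = c(CD_glucose = 1),
                      cytoplasm = c(CD_glucose = 1),
                      droplet = c(CC_odya = 1)),
    population_mixture = list(fractions = c(all = 1),
                              droplet_scale = c(all = 1)),
    noise = c(0, 0), seed = 6))
  rcc <- make_component_spectrum(comps$CC_odya, axis)
  rcd <- make_component_spectrum(comps$CD_glucose, axis)
  f <- phasor_transform(ph$stack)
  cl <- cluster_phasor(f, method = "gmm", k = 2, seed = 1,
                       references = list(CC = rcc, CD = rcd))
  u <- unmix_dual_probe(ph$stack, list(CC = rcc, CD = rcd))
  cc_phasor <- map_clusters_to_images(cl, f)$CC > 0
  cc_unmix <- u$CC > 1e-9 & u$CD < 1e-9
  expect_identical(unname(cc_phasor), unname(cc_unmix & f$valid))
})
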