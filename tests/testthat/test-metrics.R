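test_that("per-cell metrics follow the documented arithmetic", {
  # one cell of 100 px with a 20-px droplet of uniform intensity 10
  cells <- matrix(0L, 20, 20)
  cells[5:14, 5:14] <- 1L
  lipid <- matrix(0, 20, 20)
  lipid[7:10, 7:11] <- 10 # 20 signal pixels
  tab <- quantify_cells(cells, list(CH = lipid),
                        droplet_to_cell = data.frame(
                          droplet_id = 1L, cell_id = 1L, area_px = 20L,
                          centroid_row = 8.5, centroid_col = 9),
                        exclude_edge_cells = FALSE)
  expect_equal(tab$integrated_CH, 200)
  expect_equal(tab$mean_CH, 10)
  expect_equal(tab$area_fraction_CH, 20 / 100)
  expect_equal(tab$droplet_count, 1L)
  expect_equal(tab$mean_droplet_size_px, 20)
  expect_false(tab$zero_signal_CH)

  # zero-signal cell: mean defined as 0 with a flag
  tab0 <- quantify_cells(cells, list(CH = matrix(0, 20, 20)),
                         exclude_edge_cells = FALSE)
  expect_equal(tab0$integrated_CH, 0)
  expect_equal(tab0$mean_CH, 0)
  expect_equal(tab0$area_fraction_CH, 0)
  expect_true(tab0$zero_signal_CH)

  expect_error(quantify_cells(cells, list(CH = matrix(0, 5, 5))),
               "share the label grid")
})

test_that("phantom per-cell integrated lipid matches generator truth", {
  ph <- small_phantom(seed = 3, noise = c(0.02, 0.01))
  out <- phantom_component_images(ph)
  nuc <- segment_nuclei(out$images$nuclei, min_area = 10)
  cells <- outline_cells(out$field$dc, nuc)
  tab <- quantify_cells(cells, list(CH = out$images$lipid),
                        exclude_edge_cells = FALSE)
  truth_of <- match_cells_to_truth(cells, ph$truth$cell_labels)
  truth <- ph$truth$cells[match(truth_of, ph$truth$cells$cell_id), ]
  keep <- truth$integrated_droplet_signal > 0
  expect_gt(sum(keep), 0)
  expect_equal(tab$integrated_CH[keep],
               truth$integrated_droplet_signal[keep],
               tolerance = 0.05)
  # conservation: per-cell sums never exceed the total lipid image signal
  expect_lte(sum(tab$integrated_CH), sum(out$images$lipid))
})

test_that("histograms cover degenerate and bimodal inputs", {
  h1 <- population_histogram(3.2)
  expect_equal(sum(h1$count), 1)
  hsame <- population_histogram(rep(2, 25))
  expect_equal(sum(hsame$count), 25)
  expect_equal(sum(hsame$count > 0), 1)
  expect_error(population_histogram(numeric(0)), "empty")

  pop <- generate_population_intensities(c(0.5, 0.5), c(1, 3.3), 0.3,
                                         n = 500, seed = 3)
  h <- population_histogram(log(pop$intensity))
  expect_equal(sum(h$count), 500)
  # smoothed counts show two local maxima separated by a trough
  sm <- stats::filter(h$count, rep(1 / 3, 3))
  sm <- c(-Inf, sm[!is.na(sm)], -Inf) # boundary bins can be modes too
  peaks <- which(diff(sign(diff(sm))) == -2) + 1
  expect_gte(length(peaks), 2)
  trough <- min(sm[min(peaks):max(peaks)])
  expect_lt(trough, 0.5 * min(sm[peaks]))
})

test_that("mixture model detects subpopulations and recovers weights", {
  pop <- generate_population_intensities(c(0.4, 0.6), c(1, 3.3), 0.3,
                                         n = 500, seed = 7)
  fit <- classify_subpopulations(pop$intensity, seed = 1)
  expect_equal(fit$k_selected, 2)
  expect_equal(fit$weights, c(0.4, 0.6), tolerance = 0.05 / 0.4)
  expect_setequal(unique(fit$class), c("lipid-poor", "lipid-rich"))
  # lower-mean component is lipid-poor
  expect_lt(fit$means[1], fit$means[2])

  # scale invariance: classes unchanged under global intensity scaling
  fit2 <- classify_subpopulations(pop$intensity * 37.5, seed = 1)
  expect_identical(fit$class, fit2$class)
  expect_equal(fit2$means, fit$means + log(37.5), tolerance = 1e-6)

  # single component selects k = 1
  uni <- generate_population_intensities(1, 2, 0.3, n = 400, seed = 5)
  expect_equal(classify_subpopulations(uni$intensity, seed = 1)$k_selected, 1)

  expect_error(classify_subpopulations(c(rep(1, 20), 0)), "positive")
  expect_error(classify_subpopulations(rep(1.5, 5)), "insufficient")
})

test_that("weight recovery holds across seeds at 3-sigma separation", {
  ok <- 0
  for (s in 1:10) {
    pop <- generate_population_intensities(c(0.35, 0.65), c(1, 2.2), 0.35,
                                           n = 400, seed = s)
    fit <- classify_subpopulations(pop$intensity, k_candidates = 1:3,
                                   seed = 1)
    if (fit$k_selected == 2 &&
        all(abs(fit$weights - c(0.35, 0.65)) <= 0.05)) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 9)
})

test_that("population comparison reports rich-fraction shifts", {
  make_table <- function(frac_rich, n, seed) {
    pop <- generate_population_intensities(c(1 - frac_rich, frac_rich),
                                           c(1, 3.3), 0.3, n, seed)
    data.frame(cell_id = seq_len(n), integrated_CH = pop$intensity)
  }
  ta <- make_table(0.2, 400, 11)
  tb <- make_table(0.6, 400, 12)
  cmp <- compare_populations(ta, tb, "integrated_CH", seed = 1)
  expect_equal(cmp$difference, 0.4, tolerance = 0.07 / 0.4)
  expect_lt(cmp$test$p_value, 1e-4)

  same <- compare_populations(ta, ta, "integrated_CH", seed = 1)
  expect_equal(same$difference, 0)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)

  expect_error(compare_populations(ta[0, ], tb, "integrated_CH"),
               "non-empty")
  expect_error(compare_populations(ta, tb, "nope"), "unknown metric")
})
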