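test_that("volume extrapolation identities and arithmetic hold", {
  expect_equal(extrapolate_copies(123, 7, 7)$copies_per_cell, 123)
  expect_equal(extrapolate_copies(0, 1, 100)$copies_per_cell, 0)
  est <- extrapolate_copies(5e4, 10.1, 5282.5)
  expect_equal(est$copies_per_cell, 5e4 * 5282.5 / 10.1)
  expect_equal(est$se, sqrt(5e4) * 5282.5 / 10.1)
  expect_error(extrapolate_copies(10, 0, 5), "positive")
})

test_that("extrapolation is linear in count and cell volume, inverse in imaged volume", {
  base <- extrapolate_copies(100, 5, 500)$copies_per_cell
  for (f in c(0.5, 2, 10)) {
    expect_equal(extrapolate_copies(100 * f, 5, 500)$copies_per_cell,
                 base * f)
    expect_equal(extrapolate_copies(100, 5, 500 * f)$copies_per_cell,
                 base * f)
    expect_equal(extrapolate_copies(100, 5 * f, 500)$copies_per_cell,
                 base / f)
  }
})

test_that("standard curves are exact on noise-free lines", {
  curve <- fit_standard_curve(c(0, 1, 2, 4), 2 * c(0, 1, 2, 4) + 1)
  expect_equal(curve$slope, 2, tolerance = 1e-12)
  expect_equal(curve$intercept, 1, tolerance = 1e-12)
  expect_equal(curve$residual_sd, 0, tolerance = 1e-9)
  two <- fit_standard_curve(c(1, 3), c(5, 9))
  expect_equal(two$slope, 2)
  expect_equal(two$intercept, 3)
  expect_error(fit_standard_curve(c(2, 2, 2), c(1, 2, 3)), "counts equal")
})

test_that("noisy dilution series refit the slope within its standard error", {
  levels <- seq(1e4, 5e5, length.out = 50)
  slope <- 0.002; sigma <- 20
  series <- generate_dilution_series(slope, 3, levels, sigma, seed = 14)
  curve <- fit_standard_curve(series$count, series$fluorescence)
  se_slope <- sigma / sqrt(sum((levels - mean(levels))^2))
  expect_lt(abs(curve$slope - slope), 3 * se_slope)
  clean <- generate_dilution_series(2, 1, c(10, 20), 0)
  expect_equal(clean$fluorescence, 2 * c(10, 20) + 1)
})

test_that("fluorescence inversion recovers the delivered copy number", {
  curve <- fit_standard_curve(c(0, 1e6, 2e6), c(0, 1e6, 2e6))  # slope 1
  n_cells <- 1e4
  est <- copies_from_fluorescence(curve, bulk_signal = 6.6e5 * n_cells,
                                  background_signal = 0, n_cells = n_cells)
  expect_equal(est$copies_per_cell, 6.6e5)
  expect_warning(
    zero <- copies_from_fluorescence(curve, 5, 5, 10), "0 copies")
  expect_equal(zero$copies_per_cell, 0)
  bad <- fit_standard_curve(c(0, 1, 2), c(3, 2, 1))
  expect_error(copies_from_fluorescence(bad, 1, 0, 1), "slope")
})

test_that("standard-curve round trip through the generator is exact", {
  truth_per_cell <- 3.3e5
  n_cells <- 5e3
  series <- generate_dilution_series(0.0015, 40,
                                     seq(1e5, 4e9, length.out = 8), 0)
  curve <- fit_standard_curve(series$count, series$fluorescence)
  bulk <- 0.0015 * truth_per_cell * n_cells + 40 + 120
  est <- copies_from_fluorescence(curve, bulk, 120, n_cells)
  expect_equal(est$copies_per_cell, truth_per_cell, tolerance = 1e-6)
})

test_that("flow ratios scale copies by background-subtracted medians", {
  expect_equal(flow_ratio_copies(500, 500, 50, 1.1e5)$copies_per_cell, 1.1e5)
  expect_equal(flow_ratio_copies(950, 500, 50, 1e5)$copies_per_cell, 2e5)
  expect_warning(z <- flow_ratio_copies(50, 500, 50, 1e5), "0 copies")
  expect_equal(z$copies_per_cell, 0)
  expect_error(flow_ratio_copies(500, 40, 50, 1e5), "reference")
  # invariance to a common rescaling of all medians about the background
  a <- flow_ratio_copies(800, 400, 100, 7e5)$copies_per_cell
  b <- flow_ratio_copies(100 + 3 * 700, 100 + 3 * 300, 100,
                         7e5)$copies_per_cell
  expect_equal(a, b)
})

test_that("flow generator round trip recovers the target copy number", {
  med <- generate_flow_medians(target_copies = 7e5, reference_copies = 1.1e5,
                               cv = 0, seed = 4)
  est <- flow_ratio_copies(med$median_target[1], med$median_reference[1],
                           med$median_background[1], 1.1e5)
  expect_equal(est$copies_per_cell, 7e5, tolerance = 1e-9)
  noisy <- generate_flow_medians(7e5, 1.1e5, cv = 0.05, n_replicates = 3,
                                 seed = 6)
  est2 <- flow_ratio_copies(median(noisy$median_target),
                            median(noisy$median_reference),
                            median(noisy$median_background), 1.1e5)
  expect_lt(abs(est2$copies_per_cell - 7e5) / 7e5, 0.25)
})
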