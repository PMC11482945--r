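test_that("noise-only volumes produce no detections at high k_sigma", {
  v <- nano_volume(array(rnorm(32^3), dim = c(32, 32, 32)), 1)
  det <- detect_particles(v, detection_params(k_sigma = 5))
  expect_equal(nrow(det), 0)
})

test_that("noise-free rendered golds are all recovered with tight centroids", {
  sc <- gold_only_scene(n_gold = 20, seed = 4)
  det <- detect_particles(render_volume(sc), detection_params())
  expect_equal(nrow(det), 20)
  m <- match_to_ground_truth(det, sc$golds, tolerance = 1)  # one voxel
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("a rendered 5 nm sphere is sized to within one voxel", {
  spec <- scene_spec(box_size = 32, voxel_size = 1, n_targets = 0,
                     label_fraction = 0, gold_diameter = 5,
                     gold_amplitude = 10, seed = 1)
  golds <- particle_table(x = 16.2, y = 15.7, z = 16.4, diameter = 5)
  det <- detect_particles(render_volume(manual_scene(golds, spec)),
                          detection_params())
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$diameter - 5), 1)
  expect_lt(sqrt(sum((unlist(det[1, c("x", "y", "z")]) -
                        c(16.2, 15.7, 16.4))^2)), 1)
})

test_that("detection count is monotonically non-increasing in k_sigma", {
  sc <- gold_only_scene(n_gold = 10, noise_sigma = 1.5, seed = 9)
  v <- render_volume(sc)
  counts <- vapply(c(2, 3, 4, 6, 10), function(k) {
    nrow(detect_particles(v, detection_params(k_sigma = k, min_voxels = 1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("greedy matching agrees with the exhaustive assignment oracle", {
  set.seed(42)
  truth <- particle_table(x = runif(5, 0, 50), y = runif(5, 0, 50),
                          z = runif(5, 0, 50))
  det <- particle_table(x = runif(3, 0, 50), y = runif(3, 0, 50),
                        z = runif(3, 0, 50))
  tol <- 30
  m <- match_to_ground_truth(det, truth, tol)
  # oracle: enumerate all injective detection->truth assignments, keep the
  # maximum number of within-tolerance pairs
  dm <- as.matrix(dist(rbind(as.matrix(truth[, c("x", "y", "z")]),
                             as.matrix(det[, c("x", "y", "z")]))))
  dm <- dm[1:5, 6:8]
  best <- 0
  for (a in 1:5) for (b in 1:5) for (c in 1:5) {
    if (a != b && b != c && a != c) {
      ok <- sum(dm[a, 1] <= tol, dm[b, 2] <= tol, dm[c, 3] <= tol)
      best <- max(best, ok)
    }
  }
  expect_equal(m$n_matched, best)
  expect_equal(m$precision, best / 3)
  expect_equal(m$recall, best / 5)
})

test_that("degenerate matching cases follow the contract", {
  pts <- particle_table(x = c(1, 2), y = c(1, 2), z = c(1, 2))
  perfect <- match_to_ground_truth(pts, pts, tolerance = 0.5)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  none <- match_to_ground_truth(particle_table(), pts, tolerance = 1)
  expect_equal(none$recall, 0)
  expect_false(none$precision_defined)
  expect_true(is.na(none$precision))
})

test_that("diameter summaries use the sample SD", {
  tab <- particle_table(x = c(0, 1), y = 0, z = 0, diameter = c(4, 6))
  s <- summarize_diameters(tab)
  expect_equal(s$mean, 5)
  expect_equal(s$sd, sqrt(2))
  one <- summarize_diameters(particle_table(x = 0, y = 0, z = 0,
                                            diameter = 9.6))
  expect_equal(one$mean, 9.6)
  expect_true(is.na(one$sd))
  expect_error(summarize_diameters(particle_table()), "no diameters")
})

test_that("enhanced-particle diameter estimates center on the truth", {
  set.seed(1)
  d <- rnorm(1000, 9.6, 1)
  tab <- particle_table(x = seq_along(d), y = 0, z = 0, diameter = d)
  s <- summarize_diameters(tab)
  expect_lt(abs(s$mean - 9.6), 3 * 1 / sqrt(1000))
})

test_that("2-D detection sizes by equivalent-circle diameter", {
  img <- matrix(0, 64, 64)
  xc <- 32.5; yc <- 32.5; r <- 6
  for (i in 1:64) for (j in 1:64) {
    if ((i - xc)^2 + (j - yc)^2 <= r^2) img[i, j] <- 10
  }
  det <- detect_particles(nano_volume(img, 1), detection_params())
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$diameter - 2 * r), 1)
})
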