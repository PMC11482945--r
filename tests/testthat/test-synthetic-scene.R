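test_that("empty scene yields empty tables", {
  sc <- generate_labeled_scene(scene_spec(
    box_size = 32, voxel_size = 1, n_targets = 0, label_fraction = 0.5,
    seed = 1))
  expect_equal(nrow(sc$targets), 0)
  expect_equal(nrow(sc$golds), 0)
})

test_that("degenerate tether places every gold exactly at the offset radius", {
  sc <- generate_labeled_scene(scene_spec(
    box_size = 128, voxel_size = 1, n_targets = 25, label_fraction = 1,
    tether = tether_model(offset_radius = 12.9, linker_mean = 0,
                          linker_sigma = 0),
    min_separation = 10, edge_margin = 16, seed = 7))
  expect_equal(nrow(sc$golds), 25)
  tp <- as.matrix(sc$targets[match(sc$golds$parent_id, sc$targets$id),
                             c("x", "y", "z")])
  gp <- as.matrix(sc$golds[, c("x", "y", "z")])
  expect_equal(sqrt(rowSums((gp - tp)^2)), rep(12.9, 25), tolerance = 1e-12)
})

test_that("bound-gold count follows the labeling binomial", {
  sc <- generate_labeled_scene(scene_spec(
    box_size = 400, voxel_size = 1, n_targets = 200, label_fraction = 0.7,
    min_separation = 10, seed = 11))
  nb <- sum(sc$golds$bound)
  expect_within_binomial_ci(nb, 200, 0.7)
  expect_true(all(sc$golds$parent_id %in% sc$targets$id))
})

test_that("scenes are bit-reproducible from their seed", {
  spec <- scene_spec(box_size = 64, voxel_size = 1, n_targets = 15,
                     label_fraction = 0.6, n_unbound_gold = 4,
                     tether = tether_model(12.9, 1, 0.5),
                     min_separation = 8, seed = 99)
  expect_identical(generate_labeled_scene(spec), generate_labeled_scene(spec))
})

test_that("infeasible packing density errors, naming the density", {
  spec <- scene_spec(box_size = 20, voxel_size = 1, n_targets = 50,
                     label_fraction = 1, min_separation = 15, seed = 1)
  expect_error(generate_labeled_scene(spec), "packing failure")
})

test_that("mean tether reach converges to the truncated linker mean", {
  mu <- 2; sg <- 1
  spec <- scene_spec(box_size = 2000, voxel_size = 1, n_targets = 1500,
                     label_fraction = 1,
                     tether = tether_model(12.9, mu, sg), seed = 13)
  sc <- generate_labeled_scene(spec)
  tp <- as.matrix(sc$targets[match(sc$golds$parent_id, sc$targets$id),
                             c("x", "y", "z")])
  gp <- as.matrix(sc$golds[, c("x", "y", "z")])
  reach <- sqrt(rowSums((gp - tp)^2)) - 12.9
  # E[max(0, L)], L ~ N(mu, sg): closed form for the rectified Gaussian
  expect_true(all(reach > -1e-9))
  m_expect <- mu * pnorm(mu / sg) + sg * dnorm(mu / sg)
  se <- sd(reach) / sqrt(length(reach))
  expect_lt(abs(mean(reach) - m_expect), 3 * se)
})

test_that("min_separation is honored between target centers", {
  sc <- generate_labeled_scene(scene_spec(
    box_size = 100, voxel_size = 1, n_targets = 30, label_fraction = 0,
    min_separation = 12, seed = 5))
  d <- as.matrix(dist(sc$targets[, c("x", "y", "z")]))
  diag(d) <- Inf
  expect_gte(min(d), 12)
})

test_that("rendered pure-noise volume has the requested moments", {
  spec <- scene_spec(box_size = 32, voxel_size = 1, n_targets = 0,
                     label_fraction = 0, noise_sigma = 1, seed = 3)
  v <- render_volume(generate_labeled_scene(spec))
  n <- length(v$grid)
  expect_lt(abs(mean(v$grid)), 3 / sqrt(n))
  expect_lt(abs(sd(v$grid) - 1), 3 / sqrt(2 * n))
})

test_that("rasterized gold sphere matches the analytic sphere volume", {
  spec <- scene_spec(box_size = 32, voxel_size = 1, n_targets = 0,
                     label_fraction = 0, gold_diameter = 5,
                     gold_amplitude = 10, seed = 1)
  golds <- particle_table(x = 15.5, y = 15.5, z = 15.5, diameter = 5)
  v <- render_volume(manual_scene(golds, spec))
  count <- sum(v$grid > 5)
  analytic <- pi / 6 * 5^3            # voxel volume is 1 nm^3
  expect_lt(abs(count - analytic) / analytic, 0.3)
  # finer sampling shrinks the discretization error
  spec2 <- scene_spec(box_size = 64, voxel_size = 0.5, n_targets = 0,
                      label_fraction = 0, gold_diameter = 5,
                      gold_amplitude = 10, seed = 1)
  v2 <- render_volume(manual_scene(golds, spec2))
  count2 <- sum(v2$grid > 5) * 0.5^3
  expect_lt(abs(count2 - analytic) / analytic,
            abs(count - analytic) / analytic)
})

test_that("rendering is deterministic and gold outshines targets", {
  spec <- scene_spec(box_size = 48, voxel_size = 1, n_targets = 6,
                     label_fraction = 1, gold_amplitude = 10,
                     target_amplitude = 3, target_radius = 2,
                     noise_sigma = 0.5, min_separation = 12,
                     edge_margin = 14, seed = 21)
  sc <- generate_labeled_scene(spec)
  expect_identical(render_volume(sc)$grid, render_volume(sc)$grid)
  spec0 <- spec; spec0$noise_sigma <- 0
  sc0 <- sc; sc0$spec <- spec0
  v0 <- render_volume(sc0)
  gpos <- round(as.matrix(sc0$golds[, c("x", "y", "z")]) + 0.5)
  # the voxel under each gold center carries at least the gold amplitude,
  # above anything a target blob alone can reach
  expect_true(all(v0$grid[gpos] >= spec$gold_amplitude))
  expect_gt(max(v0$grid), spec$target_amplitude)
})

test_that("out-of-box particles are clipped with a log message", {
  spec <- scene_spec(box_size = 16, voxel_size = 1, n_targets = 0,
                     label_fraction = 0, gold_diameter = 5,
                     gold_amplitude = 10, seed = 1)
  golds <- particle_table(x = 30, y = 8, z = 8, diameter = 5)
  expect_message(v <- render_volume(manual_scene(golds, spec)), "clipped")
  expect_equal(max(v$grid), 0)
})
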