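# Shared fixtures and independent oracles (brute-force references kept free
# of the implementation paths they check).

# Direct O(N*M) all-pairs nearest neighbor.
brute_nearest <- function(src, dst) {
  t(vapply(seq_len(nrow(src)), function(i) {
    d <- sqrt(colSums((t(dst) - src[i, ])^2))
    j <- which.min(d)
    c(d = d[j], j = j)
  }, c(d = 0, j = 0)))
}

# Direct per-slice truncated-window mean.
brute_slice_average <- function(grid, n) {
  nz <- dim(grid)[3]
  lo_half <- (n - 1L) %/% 2L + (1L - n %% 2L)
  hi_half <- (n - 1L) %/% 2L
  out <- array(0, dim = dim(grid))
  for (k in seq_len(nz)) {
    win <- max(1L, k - lo_half):min(nz, k + hi_half)
    acc <- array(0, dim = dim(grid)[1:2])
    for (w in win) acc <- acc + grid[, , w]
    out[, , k] <- acc / length(win)
  }
  out
}

# Scene whose only bright objects are gold spheres: targets get an amplitude
# far below any detection threshold so the detector sees gold alone.
gold_only_scene <- function(n_gold = 20, box = 96, noise_sigma = 0,
                            gold_amplitude = 10, seed = 1) {
  generate_labeled_scene(scene_spec(
    box_size = box, voxel_size = 1, n_targets = n_gold, label_fraction = 1,
    tether = tether_model(offset_radius = 6, linker_mean = 0,
                          linker_sigma = 0),
    gold_diameter = 5, gold_amplitude = gold_amplitude,
    target_radius = 2, target_amplitude = 0.05,
    noise_sigma = noise_sigma, min_separation = 16, edge_margin = 14,
    seed = seed))
}

# Ground-truth scene built directly from tables (for hand-placed renders).
manual_scene <- function(golds, spec, targets = particle_table()) {
  structure(list(targets = targets, golds = golds, spec = spec),
            class = "gold_scene")
}

expect_within_binomial_ci <- function(count, n, p, level = 0.99) {
  a <- (1 - level) / 2
  lo <- stats::qbinom(a, n, p)
  hi <- stats::qbinom(1 - a, n, p)
  expect_true(count >= lo && count <= hi,
              label = sprintf("count %d in [%d, %d] (n=%d, p=%.2f)",
                              count, lo, hi, n, p))
}
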