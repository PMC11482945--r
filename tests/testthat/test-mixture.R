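test_that("a single component reduces to the sample moments", {
  set.seed(2)
  x <- rnorm(300, 9.6, 1)
  fit <- fit_diameter_mixture(x, n_components = 1)
  expect_equal(fit$means, mean(x), tolerance = 1e-6)
  expect_equal(fit$sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-6)
  expect_equal(fit$weights, 1)
})

test_that("the two gold populations are recovered from unlabeled diameters", {
  spec <- diameter_sample_spec(n = 5000, seed = 31)
  samp <- generate_diameter_sample(spec)
  fit <- fit_diameter_mixture(samp$diameter)
  se <- spec$sigmas / sqrt(spec$n * spec$weights)
  expect_lt(abs(fit$means[1] - 1.52), 3 * se[1])
  expect_lt(abs(fit$means[2] - 5.62), 3 * se[2])
  expect_lt(abs(fit$weights[1] - 0.5), 0.05)
  acc <- mean(predict(fit, samp$diameter) == samp$class)
  expect_gte(acc, 0.99)
})

test_that("well-separated spikes are recovered almost exactly", {
  set.seed(3)
  x <- c(rnorm(200, 1, 0.1), rnorm(200, 100, 0.1))
  fit <- fit_diameter_mixture(x)
  expect_equal(fit$means, c(mean(x[1:200]), mean(x[201:400])),
               tolerance = 1e-3)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-3)
})

test_that("the fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  samp <- generate_diameter_sample(diameter_sample_spec(n = 2000, seed = 17))
  fit <- fit_diameter_mixture(samp$diameter)
  ref <- mclust::Mclust(samp$diameter, G = 2, modelNames = "V",
                        verbose = FALSE)
  expect_equal(fit$means, as.numeric(ref$parameters$mean), tolerance = 0.02)
  expect_equal(fit$sds, sqrt(as.numeric(ref$parameters$variance$sigmasq)),
               tolerance = 0.05)
})

test_that("the fit is invariant to input order and equivariant to rescaling", {
  samp <- generate_diameter_sample(diameter_sample_spec(n = 1000, seed = 23))
  f1 <- fit_diameter_mixture(samp$diameter)
  f2 <- fit_diameter_mixture(rev(samp$diameter))
  expect_equal(f1$means, f2$means, tolerance = 1e-9)
  f10 <- fit_diameter_mixture(samp$diameter * 10)
  expect_equal(f10$means, f1$means * 10, tolerance = 1e-3)
  expect_equal(f10$sds, f1$sds * 10, tolerance = 1e-3)
})

test_that("parameter recovery holds across seeds", {
  for (seed in 1:10) {
    spec <- diameter_sample_spec(n = 2000, seed = seed)
    samp <- generate_diameter_sample(spec)
    fit <- fit_diameter_mixture(samp$diameter)
    se <- spec$sigmas / sqrt(spec$n * spec$weights)
    expect_lt(abs(fit$means[1] - 1.52), 4 * se[1])
    expect_lt(abs(fit$means[2] - 5.62), 4 * se[2])
  }
})

test_that("degenerate samples error, naming the zero variance", {
  expect_error(fit_diameter_mixture(rep(5, 100)), "zero variance")
  expect_error(fit_diameter_mixture(1:5), "at least")
})

test_that("classification labels and ties follow the contract", {
  fit <- structure(list(weights = c(0.5, 0.5), means = c(1, 3),
                        sds = c(0.5, 0.5), n_components = 2L,
                        data = numeric(), n = 0L, n_iter = 0L,
                        logLik = NA_real_, var_floor = 1e-4),
                   class = "size_class_model")
  cl <- classify_diameters(c(1, 3, 2), fit)
  expect_equal(cl$labels, c(1L, 2L, 1L))   # exact posterior tie at 2 -> 1
  expect_equal(rowSums(cl$posterior), rep(1, 3), tolerance = 1e-12)
})

test_that("class overlap behaves at its limits", {
  same <- structure(list(weights = c(0.5, 0.5), means = c(2, 2),
                         sds = c(1, 1), n_components = 2L),
                    class = "size_class_model")
  expect_equal(class_overlap(same), 0.5, tolerance = 1e-4)
  far <- structure(list(weights = c(0.5, 0.5), means = c(1, 1000),
                        sds = c(1, 1), n_components = 2L),
                   class = "size_class_model")
  expect_lt(class_overlap(far), 1e-10)
  paper_pops <- structure(list(weights = c(0.5, 0.5), means = c(1.52, 5.62),
                               sds = c(0.359, 0.911), n_components = 2L),
                          class = "size_class_model")
  expect_lt(class_overlap(paper_pops), 0.01)
})

test_that("model methods expose coherent summaries", {
  samp <- generate_diameter_sample(diameter_sample_spec(n = 500, seed = 2))
  fit <- fit_diameter_mixture(samp$diameter)
  co <- coef(fit)
  expect_equal(dim(co), c(2, 3))
  expect_true(co[1, "mean"] < co[2, "mean"])
  expect_equal(sum(co[, "weight"]), 1, tolerance = 1e-9)
  sims <- simulate(fit, nsim = 1000, seed = 1)
  expect_equal(simulate(fit, nsim = 1000, seed = 1), sims)
  expect_equal(mean(sims), sum(co[, "weight"] * co[, "mean"]),
               tolerance = 0.3)
  expect_s3_class(logLik(fit), "logLik")
})

test_that("generator truncation and degenerate weights behave", {
  tiny <- generate_diameter_sample(diameter_sample_spec(
    means = 3, sigmas = 1e-12, weights = 1, n = 50, seed = 1))
  expect_equal(tiny$diameter, rep(3, 50), tolerance = 1e-9)
  onesided <- generate_diameter_sample(diameter_sample_spec(
    means = c(1.52, 5.62), sigmas = c(0.359, 0.911), weights = c(1, 0),
    n = 100, seed = 1))
  expect_true(all(onesided$class == 1))
  expect_true(all(onesided$diameter > 0))
})
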