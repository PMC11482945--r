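# Synthetic 1-D fixtures: diameter mixtures, fluorescence dilution series,
# flow-cytometry median triplets.

#' Specification of a mixed diameter sample
#'
#' Defaults are the two gold populations used for size multiplexing: the
#' 1.4 nm probe measures 1.52 nm (SD 0.359 nm) and the 5 nm probe 5.62 nm
#' (SD 0.911 nm) on grid micrographs.
#'
#' @param means,sigmas per-class Normal parameters in nm (`sigmas > 0`).
#' @param weights mixing fractions, summing to 1.
#' @param n sample size.
#' @param seed integer seed.
#' @return a `diameter_sample_spec` list.
#' @export
diameter_sample_spec <- function(means = c(1.52, 5.62),
                                 sigmas = c(0.359, 0.911),
                                 weights = c(0.5, 0.5), n = 1000L,
                                 seed = 1L) {
  stopifnot(length(means) == length(sigmas),
            length(means) == length(weights),
            all(sigmas > 0), all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8,
            is_scalar_number(n), n >= 0)
  structure(list(means = as.numeric(means), sigmas = as.numeric(sigmas),
                 weights = as.numeric(weights), n = as.integer(n),
                 seed = as.integer(seed)),
            class = "diameter_sample_spec")
}

#' Draw diameters from a labeled Gaussian mixture
#'
#' Each diameter is drawn from its class Normal, truncated at > 0 by
#' redrawing; the generating class is recorded so recovery can be scored
#' against truth.
#'
#' @param spec a [diameter_sample_spec()].
#' @return data.frame with columns `diameter` (nm) and `class` (integer,
#'   1-based, in the order of `spec$means`).
#' @export
generate_diameter_sample <- function(spec) {
  stopifnot(inherits(spec, "diameter_sample_spec"))
  with_seed(spec$seed, {
    cls <- sample.int(length(spec$means), spec$n, replace = TRUE,
                      prob = spec$weights)
    d <- stats::rnorm(spec$n, spec$means[cls], spec$sigmas[cls])
    bad <- which(d <= 0)
    guard <- 0L
    while (length(bad) && guard < 1000L) {
      d[bad] <- stats::rnorm(length(bad), spec$means[cls[bad]],
                             spec$sigmas[cls[bad]])
      bad <- which(d <= 0)
      guard <- guard + 1L
    }
    if (length(bad)) d[bad] <- .Machine$double.eps
    data.frame(diameter = d, class = cls)
  })
}

#' Generate a linear fluorescence dilution series
#'
#' Emulates the standard-curve measurement: fluorescence intensity versus
#' molecule count on a straight line plus Gaussian noise.
#'
#' @param slope fluorescence units per molecule.
#' @param intercept fluorescence at zero molecules.
#' @param levels numeric vector of molecule counts (at least 2).
#' @param noise_sigma SD of additive Gaussian noise on fluorescence.
#' @param seed integer seed.
#' @return data.frame with columns `count` and `fluorescence`.
#' @export
generate_dilution_series <- function(slope, intercept, levels,
                                     noise_sigma = 0, seed = 1L) {
  stopifnot(is_scalar_number(slope), is_scalar_number(intercept),
            is.numeric(levels), length(levels) >= 2,
            is_scalar_number(noise_sigma), noise_sigma >= 0)
  with_seed(seed, {
    f <- slope * levels + intercept +
      stats::rnorm(length(levels), 0, noise_sigma)
    data.frame(count = as.numeric(levels), fluorescence = f)
  })
}

#' Generate flow-cytometry median-intensity triplets
#'
#' Emulates the readout of the ratio-to-reference copy-number protocol:
#' median fluorescence of the stained target line, of a stained reference
#' line of known copy number, and of unstained background, replicated with
#' multiplicative lognormal measurement spread.
#'
#' @param target_copies,reference_copies true copies per cell.
#' @param intensity_per_copy fluorescence units per copy.
#' @param background median background intensity (autofluorescence).
#' @param cv coefficient of variation of the replicate medians.
#' @param n_replicates number of replicate triplets.
#' @param seed integer seed.
#' @return data.frame with columns `median_target`, `median_reference`,
#'   `median_background`.
#' @export
generate_flow_medians <- function(target_copies, reference_copies,
                                  intensity_per_copy = 1e-3,
                                  background = 50, cv = 0, n_replicates = 3L,
                                  seed = 1L) {
  stopifnot(is_scalar_number(target_copies), target_copies >= 0,
            is_scalar_number(reference_copies), reference_copies > 0,
            is_scalar_number(intensity_per_copy), intensity_per_copy > 0,
            is_scalar_number(background), background >= 0,
            is_scalar_number(cv), cv >= 0, n_replicates >= 1)
  with_seed(seed, {
    jitter <- function(mu) {
      if (cv == 0) rep(mu, n_replicates)
      else mu * stats::rlnorm(n_replicates,
                              meanlog = -0.5 * log(1 + cv^2),
                              sdlog = sqrt(log(1 + cv^2)))
    }
    data.frame(
      median_target = jitter(background + target_copies * intensity_per_copy),
      median_reference = jitter(background +
                                  reference_copies * intensity_per_copy),
      median_background = jitter(background)
    )
  })
}
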