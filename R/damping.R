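# Gold-signal damping: replace outlier (gold) intensities with background
# noise so the bright gold mass does not dominate subtomogram alignment.

#' Damping parameters
#'
#' @param k SD multiplier for the outlier threshold (default 1, i.e.
#'   intensities more than one SD above the mean are replaced).
#' @param side `"high-only"` (default; only the bright tail, where gold
#'   lives on density-positive data) or `"two-sided"`.
#' @param seed integer seed for the replacement draws.
#' @return a `damping_params` list.
#' @export
damping_params <- function(k = 1, side = c("high-only", "two-sided"),
                           seed = 1L) {
  side <- match.arg(side)
  stopifnot(is_scalar_number(k), k > 0)
  structure(list(k = k, side = side, seed = as.integer(seed)),
            class = "damping_params")
}

#' Damp high-intensity (gold) signal in a subvolume
#'
#' Let mu and sigma be the mean and SD of the full grid. Voxels above
#' `mu + k*sigma` (and below `mu - k*sigma` when two-sided) are replaced by
#' independent draws from `Normal(mu_bg, sigma_bg)` computed over the
#' non-outlier voxels only, so the spikes being removed do not inflate the
#' replacement spread. All other voxels are unchanged bit-exactly.
#' Statistics are per input volume: apply this per subtomogram, not to a
#' whole tomogram.
#'
#' @param volume a density-positive [nano_volume] or numeric array.
#' @param params a [damping_params()].
#' @return list with `volume` (same type as input) and `mask` (logical
#'   array, `TRUE` at replaced voxels). A constant input (SD 0) is a no-op
#'   with a warning.
#' @export
damp_high_intensity <- function(volume, params = damping_params()) {
  stopifnot(inherits(params, "damping_params"))
  grid <- as_volume_grid(volume)
  if (!length(grid)) stop_nanotag("empty volume")
  if (is_nano_volume(volume) && volume$contrast != "density-positive") {
    stop_nanotag("damping expects density-positive contrast")
  }
  mu <- mean(grid)
  sg <- stats::sd(grid)
  mask <- array(FALSE, dim = dim(grid))
  if (!is.finite(sg) || sg == 0) {
    warning("constant volume (SD = 0): damping is a no-op", call. = FALSE)
    return(list(volume = rewrap_grid(volume, grid), mask = mask))
  }
  out_hi <- grid > mu + params$k * sg
  outlier <- if (params$side == "two-sided") {
    out_hi | grid < mu - params$k * sg
  } else {
    out_hi
  }
  if (any(outlier)) {
    bg <- grid[!outlier]
    mu_bg <- mean(bg)
    sg_bg <- if (length(bg) > 1) stats::sd(bg) else 0
    with_seed(params$seed, {
      grid[outlier] <- stats::rnorm(sum(outlier), mu_bg, sg_bg)
    })
    mask[outlier] <- TRUE
  }
  list(volume = rewrap_grid(volume, grid), mask = mask)
}
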