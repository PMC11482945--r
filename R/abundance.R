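# Per-cell copy-number estimation along three routes: imaged-volume
# extrapolation of detected particles, fluorescence standard curve, and
# flow-cytometry ratio to a reference line of known copy number.

new_abundance <- function(copies, method, inputs, se = NA_real_) {
  structure(list(copies_per_cell = copies, method = method,
                 inputs = inputs, se = se),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("<abundance_estimate> %.4g copies/cell (%s)",
              x$copies_per_cell, x$method))
  if (is.finite(x$se)) cat(sprintf(", SE %.3g", x$se))
  cat("\n")
  invisible(x)
}

#' Extrapolate copies per cell from an imaged subvolume
#'
#' `copies = n_detected * v_cell / v_imaged`, with a Poisson standard error
#' `sqrt(n_detected) * v_cell / v_imaged` (counting error only; the volume
#' ratio is treated as exact).
#'
#' @param n_detected particles detected in the imaged volume (>= 0).
#' @param v_imaged,v_cell imaged and whole-cell volumes, same units
#'   (conventionally µm^3), both > 0.
#' @return an `abundance_estimate`.
#' @examples
#' extrapolate_copies(5e4, v_imaged = 10.1, v_cell = 5282.5)
#' @export
extrapolate_copies <- function(n_detected, v_imaged, v_cell) {
  stopifnot(is_scalar_number(n_detected), n_detected >= 0)
  if (!is_scalar_number(v_imaged) || v_imaged <= 0 ||
      !is_scalar_number(v_cell) || v_cell <= 0) {
    stop_nanotag("volumes must be positive")
  }
  ratio <- v_cell / v_imaged
  new_abundance(n_detected * ratio, "volume_extrapolation",
                list(n_detected = n_detected, v_imaged = v_imaged,
                     v_cell = v_cell),
                se = sqrt(n_detected) * ratio)
}

#' Fit a fluorescence standard curve
#'
#' Ordinary least squares of fluorescence on molecule count; exact on
#' noise-free linear data.
#'
#' @param counts molecule counts (at least 2 distinct levels).
#' @param fluorescence measured intensities, same length.
#' @return a `standard_curve`: `slope`, `intercept`, `residual_sd`, `n`.
#' @export
fit_standard_curve <- function(counts, fluorescence) {
  stopifnot(length(counts) == length(fluorescence), length(counts) >= 2)
  if (length(unique(counts)) < 2) {
    stop_nanotag("all counts equal: cannot fit a line")
  }
  fit <- stats::lm(fluorescence ~ counts)
  # noise-free standards are legitimate here; silence lm's perfect-fit note
  res_sd <- if (length(counts) > 2) {
    suppressWarnings(summary(fit)$sigma)
  } else {
    0
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = res_sd, n = length(counts), fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> fluorescence = %.4g * count + %.4g (n = %d, residual SD %.3g)\n",
              x$slope, x$intercept, x$n, x$residual_sd))
  invisible(x)
}

#' Copies per cell from a bulk fluorescence measurement
#'
#' Inverts the standard curve on the background-subtracted bulk signal and
#' divides by the number of cells:
#' `copies = ((bulk - background - intercept) / slope) / n_cells`.
#' A negative numerator yields 0 with a warning.
#'
#' @param curve a [fit_standard_curve()] result with positive slope.
#' @param bulk_signal,background_signal bulk fluorescence of labeled cells
#'   and of matched unlabeled cells.
#' @param n_cells number of cells in the bulk measurement (> 0).
#' @return an `abundance_estimate`; SE propagates the curve residual SD
#'   through the inversion when available.
#' @export
copies_from_fluorescence <- function(curve, bulk_signal, background_signal,
                                     n_cells) {
  stopifnot(inherits(curve, "standard_curve"),
            is_scalar_number(bulk_signal), is_scalar_number(background_signal),
            is_scalar_number(n_cells), n_cells > 0)
  if (curve$slope <= 0) stop_nanotag("standard curve slope must be > 0")
  num <- bulk_signal - background_signal - curve$intercept
  if (num <= 0) {
    warning("signal at or below background: reporting 0 copies",
            call. = FALSE)
    num <- 0
  }
  copies <- (num / curve$slope) / n_cells
  se <- (curve$residual_sd / curve$slope) / n_cells
  new_abundance(copies, "fluorescence_standard_curve",
                list(curve = curve[c("slope", "intercept", "residual_sd", "n")],
                     bulk_signal = bulk_signal,
                     background_signal = background_signal,
                     n_cells = n_cells),
                se = se)
}

#' Copies per cell from flow-cytometry medians and a reference line
#'
#' The ratio-to-reference protocol: with a reference cell line of known
#' copy number stained identically,
#' `copies = reference_copies * (median_target - median_background) /
#' (median_reference - median_background)`.
#' A target at or below background yields 0 with a warning; a reference at
#' or below background is an error (the assay is uninformative).
#'
#' @param median_target,median_reference,median_background median
#'   fluorescence intensities of the target line, reference line and
#'   unstained background.
#' @param reference_copies known copies per cell of the reference (> 0).
#' @return an `abundance_estimate`.
#' @export
flow_ratio_copies <- function(median_target, median_reference,
                              median_background, reference_copies) {
  stopifnot(is_scalar_number(median_target),
            is_scalar_number(median_reference),
            is_scalar_number(median_background),
            is_scalar_number(reference_copies), reference_copies > 0)
  if (median_reference <= median_background) {
    stop_nanotag("reference median at or below background: ",
                 "cannot form the reference ratio")
  }
  num <- median_target - median_background
  if (num <= 0) {
    warning("target median at or below background: reporting 0 copies",
            call. = FALSE)
    num <- 0
  }
  copies <- reference_copies * num /
    (median_reference - median_background)
  new_abundance(copies, "flow_ratio",
                list(median_target = median_target,
                     median_reference = median_reference,
                     median_background = median_background,
                     reference_copies = reference_copies))
}
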