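# Elementary volume transforms used across visualization and preprocessing.

#' Normalize a volume to mean 0, SD 1
#'
#' A constant volume cannot be scaled; it is returned as all zeros with a
#' warning.
#'
#' @param volume a [nano_volume] or numeric array.
#' @return same type as the input, normalized.
#' @export
normalize_volume <- function(volume) {
  grid <- as_volume_grid(volume)
  if (!length(grid)) stop_nanotag("cannot normalize an empty volume")
  s <- stats::sd(grid)
  if (!is.finite(s) || s == 0) {
    warning("constant volume: normalization returns all zeros",
            call. = FALSE)
    out <- array(0, dim = dim(grid))
  } else {
    out <- (grid - mean(grid)) / s
  }
  rewrap_grid(volume, out)
}

#' Average neighboring slices of a volume
#'
#' Each output slice (along the third axis) is the mean of a centered window
#' of `n` input slices; windows are truncated at the first and last slices,
#' so output depth equals input depth. Slice averaging is the standard
#' signal-to-noise boost applied when inspecting small gold in tomogram
#' sections (ten slices in the source workflow this reimplements).
#'
#' @param volume a [nano_volume] or 3-D array.
#' @param n window length in slices (`1 <= n <=` slice count); `n = 1` is
#'   the identity. For even `n` the window extends one slice further below
#'   than above the center.
#' @return same type as input.
#' @export
average_neighboring_slices <- function(volume, n) {
  grid <- as_volume_grid(volume)
  if (length(dim(grid)) != 3L) stop_nanotag("slice averaging needs a 3-D volume")
  nz <- dim(grid)[3]
  if (!is_scalar_number(n) || n < 1) stop_nanotag("`n` must be >= 1")
  n <- as.integer(n)
  if (n > nz) stop_nanotag("`n` exceeds slice count (", nz, ")")
  lo_half <- (n - 1L) %/% 2L + (1L - n %% 2L)  # extra slice below for even n
  hi_half <- (n - 1L) %/% 2L
  out <- array(0, dim = dim(grid))
  for (k in seq_len(nz)) {
    win <- max(1L, k - lo_half):min(nz, k + hi_half)
    sl <- grid[, , win, drop = FALSE]
    out[, , k] <- rowMeans(matrix(sl, nrow = prod(dim(grid)[1:2])))
  }
  rewrap_grid(volume, out)
}

#' Invert the contrast of a volume
#'
#' Reflects intensities about their mean (`out = 2*mean - in`), turning
#' black-on-white into white-on-black while preserving the mean. Applying it
#' twice restores the input; on a [nano_volume] the contrast flag is
#' flipped.
#'
#' @param volume a [nano_volume] or numeric array.
#' @return same type as input.
#' @export
invert_contrast <- function(volume) {
  grid <- as_volume_grid(volume)
  m <- mean(grid)
  out <- rewrap_grid(volume, 2 * m - grid)
  if (is_nano_volume(out)) {
    out$contrast <- if (out$contrast == "density-positive") {
      "density-negative"
    } else {
      "density-positive"
    }
  }
  out
}

rewrap_grid <- function(template, grid) {
  if (is_nano_volume(template)) {
    template$grid <- grid
    template
  } else {
    grid
  }
}
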