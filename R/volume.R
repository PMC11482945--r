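#' Intensity volume with physical metadata
#'
#' A `nano_volume` couples a 2-D or 3-D intensity grid with the physical
#' voxel size (nm), a contrast convention and a physical origin. The contrast
#' convention records whether high density maps to high voxel values
#' (`"density-positive"`, the convention all detection code assumes) or to
#' low values (`"density-negative"`, typical of raw cryo-EM reconstructions).
#'
#' Grid axes are ordered (x, y, z) with x fastest-varying, matching R's
#' column-major layout; voxel indices are 0-based in the coordinate
#' convention, and the center of voxel `i` lies at `(i + 0.5) * voxel_size`
#' nm from the origin.
#'
#' @param grid numeric matrix (2-D) or 3-D array of intensities.
#' @param voxel_size voxel edge length in nm (> 0).
#' @param contrast `"density-positive"` or `"density-negative"`.
#' @param origin physical offset of the box corner in nm (length 2 or 3).
#' @return an object of class `nano_volume`.
#' @examples
#' v <- nano_volume(array(rnorm(8^3), dim = c(8, 8, 8)), voxel_size = 1)
#' dim(v$grid)
#' @export
nano_volume <- function(grid, voxel_size,
                        contrast = c("density-positive", "density-negative"),
                        origin = NULL) {
  contrast <- match.arg(contrast)
  if (is.vector(grid)) stop_nanotag("`grid` must be a matrix or 3-D array")
  nd <- length(dim(grid))
  if (!is.numeric(grid) || !(nd %in% c(2L, 3L))) {
    stop_nanotag("`grid` must be a numeric 2-D or 3-D array")
  }
  if (any(dim(grid) < 1L)) stop_nanotag("all grid dimensions must be >= 1")
  if (!is_scalar_number(voxel_size) || voxel_size <= 0) {
    stop_nanotag("`voxel_size` must be a positive number (nm)")
  }
  if (is.null(origin)) origin <- rep(0, nd)
  stopifnot(length(origin) == nd, all(is.finite(origin)))
  structure(
    list(grid = grid, voxel_size = as.numeric(voxel_size),
         contrast = contrast, origin = as.numeric(origin)),
    class = "nano_volume"
  )
}

is_nano_volume <- function(x) inherits(x, "nano_volume")

as_volume_grid <- function(volume) {
  if (is_nano_volume(volume)) volume$grid else volume
}

#' @export
print.nano_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<nano_volume> %s voxels, %.4g nm/voxel, %s\n",
              paste(d, collapse = " x "), x$voxel_size, x$contrast))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$grid), max(x$grid), mean(x$grid)))
  invisible(x)
}

#' @export
dim.nano_volume <- function(x) dim(x$grid)
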