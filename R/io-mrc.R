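# Minimal MRC2014 reader/writer, mode 2 (32-bit float) only.
# Axis order on disk is (x fastest, then y, then z), which maps directly onto
# R's column-major array with dim = c(nx, ny, nz). Cell dimensions are stored
# in Angstrom per the format; the in-memory voxel size is nm.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC volume
#'
#' Reads an MRC2014 file (mode 2, 32-bit float) into a [nano_volume]. The
#' voxel size is recovered from the header cell dimensions (`cella / mx`,
#' Angstrom) and converted to nm. Files whose data block is shorter than the
#' header promises raise an error rather than returning partial data.
#'
#' @param path path to an MRC file.
#' @param contrast contrast convention to attach; raw cryo-EM reconstructions
#'   are usually `"density-negative"`, rendered synthetic scenes
#'   `"density-positive"` (the default).
#' @return a [nano_volume]; a single-section file (`nz == 1`) is returned as
#'   a 2-D volume.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path,
                        contrast = c("density-positive", "density-negative")) {
  contrast <- match.arg(contrast)
  if (!file.exists(path)) stop_nanotag("no such file: ", path)
  size <- file.info(path)$size
  if (size < MRC_HEADER_BYTES) {
    stop_nanotag("malformed MRC header: file shorter than 1024 bytes")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  mode <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 3L, size = 4L, endian = "little") # nxstart..
  mxyz <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  cella <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  if (any(nxyz < 1L) || any(nxyz > 1e5)) {
    stop_nanotag("malformed MRC header: implausible dimensions ",
                 paste(nxyz, collapse = "x"))
  }
  if (mode != 2L) {
    stop_nanotag("unsupported MRC mode ", mode, " (only mode 2, float32)")
  }
  n <- prod(as.numeric(nxyz))
  if (size < MRC_HEADER_BYTES + 4 * n) {
    stop_nanotag("truncated MRC file: header promises ", n,
                 " voxels but data block is short")
  }
  if (any(mxyz < 1L)) mxyz <- nxyz
  voxel_ang <- cella[1] / mxyz[1]
  if (!is.finite(voxel_ang) || voxel_ang <= 0) {
    stop_nanotag("malformed MRC header: non-positive voxel size")
  }
  seek(con, MRC_HEADER_BYTES)
  vals <- readBin(con, "numeric", n, size = 4L, endian = "little")
  if (length(vals) < n) stop_nanotag("truncated MRC file: short read")
  grid <- if (nxyz[3] == 1L) {
    matrix(vals, nrow = nxyz[1], ncol = nxyz[2])
  } else {
    array(vals, dim = nxyz)
  }
  nano_volume(grid, voxel_size = voxel_ang / 10, contrast = contrast)
}

#' Write an MRC volume
#'
#' Writes a [nano_volume] (or bare array) as MRC2014 mode 2 (float32), with
#' the voxel size encoded in the header cell dimensions in Angstrom. The
#' round trip through [read_volume()] preserves grid values to float32
#' precision and the voxel size to float precision.
#'
#' @param volume a [nano_volume], or a numeric matrix/array (then
#'   `voxel_size` must be given).
#' @param path output path.
#' @param voxel_size voxel size in nm, used only when `volume` is a bare
#'   array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size = NULL) {
  if (!is_nano_volume(volume)) {
    if (is.null(voxel_size)) {
      stop_nanotag("`voxel_size` required when writing a bare array")
    }
    volume <- nano_volume(volume, voxel_size)
  }
  grid <- volume$grid
  d <- dim(grid)
  if (length(d) == 2L) d <- c(d, 1L)
  vox_ang <- volume$voxel_size * 10
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                               # nx ny nz
  wi(2L)                              # mode 2 = float32
  wi(c(0L, 0L, 0L))                   # nxstart
  wi(d)                               # mx my mz
  wf(d * vox_ang)                     # cella (Angstrom)
  wf(c(90, 90, 90))                   # cellb
  wi(c(1L, 2L, 3L))                   # mapc mapr maps
  wf(c(min(grid), max(grid), mean(grid)))
  wi(0L)                              # ispg
  wi(0L)                              # nsymbt
  wi(rep(0L, 25L))                    # extra
  wf(c(0, 0, 0))                      # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # machst, little-endian
  wf(stats::sd(grid))                 # rms
  wi(0L)                              # nlabl
  writeBin(raw(800L), con)            # labels
  writeBin(as.numeric(grid), con, size = 4L, endian = "little")
  invisible(path)
}
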