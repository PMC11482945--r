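# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-stage seed derivation from one global seed (Lehmer step);
# keeps derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + 7919 * stage) %% 2147483647)
}

stop_nanotag <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Pixels spanned by a particle at a given sampling
#'
#' Sampling sanity check used when planning acquisition: the number of pixels
#' across a particle of a given physical diameter at a given pixel size. A
#' 1.4 nm gold moiety imaged at 1.068 A/pixel spans about 13 pixels.
#'
#' @param diameter_nm particle diameter in nm.
#' @param pixel_size_nm pixel (voxel) size in nm.
#' @return number of pixels spanned (not rounded).
#' @examples
#' pixel_span(1.4, 0.1068)
#' @export
pixel_span <- function(diameter_nm, pixel_size_nm) {
  stopifnot(is_scalar_number(diameter_nm), diameter_nm > 0,
            is_scalar_number(pixel_size_nm), pixel_size_nm > 0)
  diameter_nm / pixel_size_nm
}
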