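# Ground-truthed synthetic scenes: macromolecule proxies carrying gold tags
# tethered at a fixed radial offset plus a flexible-linker displacement.

#' Tether geometry linking a target to its gold tag
#'
#' The gold center sits at `offset_radius + max(0, L)` nm from the target
#' center, in a uniformly random direction, where `L ~ Normal(linker_mean,
#' linker_sigma)` models the flexible linker. The default offset of 12.9 nm
#' is the distance from the center of a ribosome to the last ordered residue
#' of L29, the attachment site of the HaloTag in the ribosome labeling
#' system this package quantifies.
#'
#' @param offset_radius structural offset in nm (>= 0).
#' @param linker_mean,linker_sigma linker-length distribution in nm
#'   (`linker_sigma >= 0`).
#' @return a `tether_model` list.
#' @export
tether_model <- function(offset_radius = 12.9, linker_mean = 0,
                         linker_sigma = 0) {
  stopifnot(is_scalar_number(offset_radius), offset_radius >= 0,
            is_scalar_number(linker_mean),
            is_scalar_number(linker_sigma), linker_sigma >= 0)
  structure(list(offset_radius = offset_radius, linker_mean = linker_mean,
                 linker_sigma = linker_sigma), class = "tether_model")
}

#' Specification of a synthetic gold-labeled scene
#'
#' Describes a tomogram-like box containing `n_targets` macromolecule
#' proxies (rendered as Gaussian blobs), each carrying a tethered gold
#' sphere with probability `label_fraction`, plus unbound background gold,
#' additive Gaussian noise and an optional isotropic PSF blur.
#'
#' @param box_size voxels per axis; a single integer or length-3 vector.
#' @param voxel_size nm per voxel.
#' @param n_targets number of target particles.
#' @param label_fraction probability in \[0, 1\] that a target carries gold.
#' @param tether a [tether_model()].
#' @param gold_diameter gold sphere diameter in nm.
#' @param gold_amplitude intensity of rendered gold (must exceed
#'   `target_amplitude`; gold dominates contrast).
#' @param target_radius Gaussian-blob sigma of the target proxy, nm.
#' @param target_amplitude peak intensity of the target blob.
#' @param n_unbound_gold count of background (free) gold particles.
#' @param noise_sigma SD of additive Gaussian noise (intensity units).
#' @param psf_sigma isotropic Gaussian PSF sigma in nm; 0 disables blur.
#' @param min_separation minimum pairwise distance between target centers,
#'   nm.
#' @param edge_margin inset from the box faces (nm) inside which target
#'   centers are placed; 0 places targets uniformly in the whole box. A
#'   margin of at least `offset_radius + linker reach + gold radius` keeps
#'   tethered gold renderable inside the box.
#' @param seed integer seed; every draw in the scene derives from it.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(box_size, voxel_size, n_targets, label_fraction,
                       tether = tether_model(), gold_diameter = 5,
                       gold_amplitude = 10, target_radius = 5,
                       target_amplitude = 3, n_unbound_gold = 0,
                       noise_sigma = 0, psf_sigma = 0, min_separation = 0,
                       edge_margin = 0, seed = 1L) {
  if (length(box_size) == 1L) box_size <- rep(box_size, 3L)
  stopifnot(length(box_size) == 3L, all(box_size >= 1),
            is_scalar_number(voxel_size), voxel_size > 0,
            is_scalar_number(n_targets), n_targets >= 0,
            is_scalar_number(label_fraction),
            label_fraction >= 0, label_fraction <= 1,
            inherits(tether, "tether_model"),
            is_scalar_number(gold_diameter), gold_diameter > 0,
            is_scalar_number(target_radius), target_radius > 0,
            is_scalar_number(n_unbound_gold), n_unbound_gold >= 0,
            is_scalar_number(noise_sigma), noise_sigma >= 0,
            is_scalar_number(psf_sigma), psf_sigma >= 0,
            is_scalar_number(min_separation), min_separation >= 0,
            is_scalar_number(edge_margin), edge_margin >= 0)
  if (!(gold_amplitude > target_amplitude && target_amplitude > 0)) {
    stop_nanotag("need gold_amplitude > target_amplitude > 0 ",
                 "(gold dominates contrast)")
  }
  structure(
    list(box_size = as.integer(box_size), voxel_size = voxel_size,
         n_targets = as.integer(n_targets), label_fraction = label_fraction,
         tether = tether, gold_diameter = gold_diameter,
         gold_amplitude = gold_amplitude, target_radius = target_radius,
         target_amplitude = target_amplitude,
         n_unbound_gold = as.integer(n_unbound_gold),
         noise_sigma = noise_sigma, psf_sigma = psf_sigma,
         min_separation = min_separation, edge_margin = edge_margin,
         seed = as.integer(seed)),
    class = "scene_spec")
}

# Random-sequential placement of n points with pairwise min distance,
# uniform in [lo, hi] per axis. Errors after a bounded retry budget.
place_separated <- function(n, lo, hi, min_sep, max_tries = 200L) {
  pts <- matrix(numeric(0), ncol = 3)
  if (n == 0L) return(pts)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- stats::runif(3, lo, hi)
      if (!nrow(pts) || min_sep <= 0 ||
          min(sqrt(colSums((t(pts) - p)^2))) >= min_sep) {
        pts <- rbind(pts, p)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop_nanotag(sprintf(
        paste0("packing failure: could not place target %d of %d with ",
               "min_separation %.3g nm in a %.3g x %.3g x %.3g nm box ",
               "(density too high)"),
        i, n, min_sep, hi[1] - lo[1], hi[2] - lo[2], hi[3] - lo[3]))
    }
  }
  pts
}

random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  nrm <- sqrt(rowSums(v^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    v[zero, ] <- matrix(rep(c(1, 0, 0), sum(zero)), ncol = 3, byrow = TRUE)
    nrm[zero] <- 1
  }
  v / nrm
}

#' Generate a ground-truthed labeled scene
#'
#' Places target centers uniformly (with optional minimum separation and
#' edge margin), labels each with probability `label_fraction`, puts each
#' bound gold at `offset_radius + max(0, linker draw)` nm from its parent in
#' a uniformly random direction, and scatters unbound gold uniformly in the
#' box. Fully reproducible from `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return a `gold_scene` list with `targets` and `golds` particle tables
#'   (positions in nm) and the spec. Bound golds carry `bound = TRUE` and
#'   `parent_id`; target class labels are `NA`.
#' @examples
#' sc <- generate_labeled_scene(scene_spec(
#'   box_size = 64, voxel_size = 1, n_targets = 10, label_fraction = 1,
#'   min_separation = 12, edge_margin = 16, seed = 42))
#' nrow(sc$golds)
#' @export
generate_labeled_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  box_nm <- spec$box_size * spec$voxel_size
  lo <- rep(spec$edge_margin, 3)
  hi <- box_nm - spec$edge_margin
  if (spec$n_targets > 0 && any(hi <= lo)) {
    stop_nanotag("edge_margin leaves no room for targets")
  }
  with_seed(spec$seed, {
    tp <- place_separated(spec$n_targets, lo, hi, spec$min_separation)
    targets <- particle_table(x = tp[, 1], y = tp[, 2], z = tp[, 3])
    labeled <- if (spec$n_targets) {
      stats::runif(spec$n_targets) < spec$label_fraction
    } else {
      logical()
    }
    nb <- sum(labeled)
    bound <- if (nb) {
      reach <- spec$tether$offset_radius +
        pmax(0, stats::rnorm(nb, spec$tether$linker_mean,
                             spec$tether$linker_sigma))
      ctr <- tp[labeled, , drop = FALSE] + reach * random_unit_vectors(nb)
      data.frame(x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                 bound = TRUE, parent_id = targets$id[labeled])
    } else {
      data.frame(x = numeric(), y = numeric(), z = numeric(),
                 bound = logical(), parent_id = integer())
    }
    free <- if (spec$n_unbound_gold) {
      u <- matrix(stats::runif(3 * spec$n_unbound_gold, 0, rep(box_nm, each = spec$n_unbound_gold)),
                  ncol = 3)
      data.frame(x = u[, 1], y = u[, 2], z = u[, 3],
                 bound = FALSE, parent_id = NA_integer_)
    } else {
      data.frame(x = numeric(), y = numeric(), z = numeric(),
                 bound = logical(), parent_id = integer())
    }
    g <- rbind(bound, free)
    golds <- particle_table(x = g$x, y = g$y, z = g$z,
                            diameter = spec$gold_diameter,
                            bound = g$bound, parent_id = g$parent_id)
    structure(list(targets = targets, golds = golds, spec = spec),
              class = "gold_scene")
  })
}

#' @export
print.gold_scene <- function(x, ...) {
  cat(sprintf("<gold_scene> %d targets, %d golds (%d bound, %d unbound)\n",
              nrow(x$targets), nrow(x$golds),
              sum(x$golds$bound %in% TRUE), sum(x$golds$bound %in% FALSE)))
  invisible(x)
}

# Separable Gaussian blur along each axis (truncated at 4 sigma).
gaussian_blur <- function(grid, sigma_vox) {
  if (sigma_vox <= 0) return(grid)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(grid)
  for (axis in seq_along(d)) {
    grid <- apply_along(grid, axis, function(v) {
      stats::filter(c(rep(v[1], r), v, rep(v[length(v)], r)), k,
                    sides = 2)[(r + 1):(r + length(v))]
    })
  }
  grid
}

apply_along <- function(grid, axis, fn) {
  d <- dim(grid)
  perm <- c(axis, setdiff(seq_along(d), axis))
  g <- aperm(grid, perm)
  m <- matrix(g, nrow = d[axis])
  m <- apply(m, 2, fn)
  g <- array(m, dim = d[perm])
  aperm(g, order(perm))
}

#' Render a scene specification into an intensity volume
#'
#' Rasterizes the ground truth into a density-positive volume: targets as
#' isotropic Gaussian blobs (sigma `target_radius`, peak `target_amplitude`)
#' and golds as uniform solid spheres of `gold_diameter` at
#' `gold_amplitude`, reflecting the condensed high-mass contrast of gold
#' against diffuse protein density. The noiseless signal is optionally
#' blurred with an isotropic Gaussian PSF, then Gaussian noise of SD
#' `noise_sigma` is added. Deterministic given the scene seed. Particles
#' extending beyond the box are clipped (a message flags them).
#'
#' @param truth a `gold_scene` from [generate_labeled_scene()].
#' @return a [nano_volume] (contrast `"density-positive"`).
#' @export
render_volume <- function(truth) {
  stopifnot(inherits(truth, "gold_scene"))
  spec <- truth$spec
  d <- spec$box_size
  vox <- spec$voxel_size
  grid <- array(0, dim = d)
  box_nm <- d * vox
  clipped <- 0L

  paint <- function(center, radius_nm, fn) {
    # voxel i (1-based) has center (i - 0.5) * vox
    lo <- pmax(1L, floor(center / vox - radius_nm / vox - 1) + 1L)
    hi <- pmin(d, ceiling(center / vox + radius_nm / vox + 1))
    if (any(lo > hi)) {
      clipped <<- clipped + 1L
      return()
    }
    if (any(center < radius_nm) || any(center > box_nm - radius_nm)) {
      clipped <<- clipped + 1L
    }
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    cx <- (ix - 0.5) * vox - center[1]
    cy <- (iy - 0.5) * vox - center[2]
    cz <- (iz - 0.5) * vox - center[3]
    r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
    grid[ix, iy, iz] <<- grid[ix, iy, iz] + fn(r2)
  }

  tpos <- positions_matrix(truth$targets)
  for (i in seq_len(nrow(tpos))) {
    paint(tpos[i, ], 4 * spec$target_radius, function(r2) {
      spec$target_amplitude * exp(-r2 / (2 * spec$target_radius^2))
    })
  }
  gpos <- positions_matrix(truth$golds)
  gr <- spec$gold_diameter / 2
  for (i in seq_len(nrow(gpos))) {
    paint(gpos[i, ], gr, function(r2) spec$gold_amplitude * (r2 <= gr^2))
  }
  if (clipped > 0L) {
    message(sprintf("render_volume: %d particle(s) clipped at box edge",
                    clipped))
  }
  if (spec$psf_sigma > 0) grid <- gaussian_blur(grid, spec$psf_sigma / vox)
  if (spec$noise_sigma > 0) {
    with_seed(derive_seed(spec$seed, 101L), {
      grid <- grid + array(stats::rnorm(prod(d), 0, spec$noise_sigma), dim = d)
    })
  }
  nano_volume(grid, voxel_size = vox, contrast = "density-positive")
}
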