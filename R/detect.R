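# Gold particle detection: global threshold + connected components.
# Gold's high atomic number makes it the brightest density in the volume, so
# a global mean + k*SD threshold isolates it reliably.

#' Detection parameters
#'
#' @param k_sigma threshold multiplier: threshold = grid mean +
#'   `k_sigma` * grid SD on density-positive data (default 4).
#' @param min_voxels minimum connected-component size in voxels (>= 1).
#' @param max_voxels optional upper size cap (default `Inf`).
#' @param connectivity `"full"` (face + edge + corner, the default) or
#'   `"face"`.
#' @return a `detection_params` list.
#' @export
detection_params <- function(k_sigma = 4, min_voxels = 5L, max_voxels = Inf,
                             connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  stopifnot(is_scalar_number(k_sigma), k_sigma > 0,
            is_scalar_number(min_voxels), min_voxels >= 1,
            is.numeric(max_voxels), max_voxels >= min_voxels)
  structure(list(k_sigma = k_sigma, min_voxels = as.integer(min_voxels),
                 max_voxels = max_voxels, connectivity = connectivity),
            class = "detection_params")
}

neighbor_offsets <- function(nd, connectivity) {
  if (connectivity == "face") {
    off <- diag(1, nd)
  } else {
    grids <- rep(list(-1:1), nd)
    off <- as.matrix(expand.grid(grids))
    # keep the lexicographically-positive half so each pair appears once
    keep <- apply(off, 1, function(o) {
      nz <- which(o != 0)
      length(nz) > 0 && o[max(nz)] > 0
    })
    off <- off[keep, , drop = FALSE]
  }
  storage.mode(off) <- "integer"
  off
}

# Label connected suprathreshold voxels via the adjacency graph.
label_components <- function(mask_idx, dims, connectivity) {
  nd <- length(dims)
  coords <- arrayInd(mask_idx, dims)
  strides <- cumprod(c(1L, dims[-nd]))
  offs <- neighbor_offsets(nd, connectivity)
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- sweep(coords, 2L, o, `+`)
    valid <- rep(TRUE, nrow(nb))
    for (a in seq_len(nd)) {
      valid <- valid & nb[, a] >= 1L & nb[, a] <= dims[a]
    }
    if (!any(valid)) next
    nb_lin <- as.integer((nb[valid, , drop = FALSE] - 1L) %*% strides) + 1L
    hit <- match(nb_lin, mask_idx)
    ok <- !is.na(hit)
    if (any(ok)) {
      edges <- c(edges, rbind(which(valid)[ok], hit[ok]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(mask_idx),
                          directed = FALSE)
  igraph::components(g)$membership
}

#' Detect high-contrast particles by thresholded connected components
#'
#' Voxels above `mean + k_sigma * SD` of the whole grid are grouped into
#' connected components; components within the size window become particle
#' records with intensity-weighted centroid (nm), equivalent-sphere diameter
#' `(6 V / pi)^(1/3)` in 3-D (equivalent-circle `2 sqrt(A / pi)` in 2-D)
#' from the component's physical volume/area, and peak intensity.
#'
#' @param volume a density-positive [nano_volume] (invert first otherwise),
#'   or a bare array with `voxel_size`.
#' @param params a [detection_params()].
#' @param voxel_size nm per voxel when `volume` is a bare array.
#' @return a `particle_table` (empty when nothing passes the filters).
#' @examples
#' sc <- generate_labeled_scene(scene_spec(
#'   box_size = 48, voxel_size = 1, n_targets = 4, label_fraction = 1,
#'   gold_diameter = 5, min_separation = 16, edge_margin = 12, seed = 3))
#' det <- detect_particles(render_volume(sc), detection_params())
#' nrow(det)
#' @export
detect_particles <- function(volume, params = detection_params(),
                             voxel_size = NULL) {
  stopifnot(inherits(params, "detection_params"))
  if (!is_nano_volume(volume)) {
    if (is.null(voxel_size)) stop_nanotag("bare array needs `voxel_size`")
    volume <- nano_volume(volume, voxel_size)
  }
  if (volume$contrast != "density-positive") {
    stop_nanotag("detection expects density-positive contrast; ",
                 "apply invert_contrast() first")
  }
  grid <- volume$grid
  if (!length(grid)) stop_nanotag("empty volume")
  dims <- dim(grid)
  nd <- length(dims)
  thr <- mean(grid) + params$k_sigma * stats::sd(grid)
  mask_idx <- which(grid > thr)
  if (!length(mask_idx)) return(particle_table())
  memb <- label_components(mask_idx, dims, params$connectivity)
  sizes <- tabulate(memb)
  keep_comp <- which(sizes >= params$min_voxels & sizes <= params$max_voxels)
  if (!length(keep_comp)) return(particle_table())
  sel <- memb %in% keep_comp
  idx <- mask_idx[sel]
  grp <- match(memb[sel], keep_comp)
  vals <- grid[idx]
  coords <- arrayInd(idx, dims)                       # 1-based voxel indices
  pos_nm <- (coords - 0.5) * volume$voxel_size        # voxel centers
  wsum <- rowsum(vals, grp)[, 1]
  cen <- rowsum(pos_nm * vals, grp) / wsum
  nvox <- tabulate(grp, nbins = length(keep_comp))
  peak <- vapply(split(vals, grp), max, numeric(1))
  if (nd == 3L) {
    vol_nm3 <- nvox * volume$voxel_size^3
    diam <- (6 * vol_nm3 / pi)^(1 / 3)
    zc <- cen[, 3]
  } else {
    area_nm2 <- nvox * volume$voxel_size^2
    diam <- 2 * sqrt(area_nm2 / pi)
    zc <- rep(0, length(nvox))
  }
  particle_table(x = cen[, 1], y = cen[, 2], z = zc,
                 diameter = diam, peak_intensity = peak)
}

#' Score detections against ground truth
#'
#' Greedy nearest-pair matching: candidate (truth, detection) pairs within
#' `tolerance` are accepted in order of increasing distance, each record
#' used at most once. Precision is matched/detected, recall matched/truth.
#' With zero detections, recall is 0 and precision is undefined
#' (`precision = NA`, `precision_defined = FALSE`).
#'
#' @param detected,truth particle tables (positions in nm).
#' @param tolerance maximum match distance in nm (> 0).
#' @return list with `precision`, `precision_defined`, `recall`, `n_matched`
#'   and a `pairs` data.frame (`truth_id`, `detected_id`, `distance`).
#' @export
match_to_ground_truth <- function(detected, truth, tolerance) {
  stopifnot(is_scalar_number(tolerance), tolerance > 0)
  nd <- nrow(detected)
  nt <- nrow(truth)
  pairs <- data.frame(truth_id = integer(), detected_id = integer(),
                      distance = numeric())
  if (nd > 0 && nt > 0) {
    dm <- pair_distances(positions_matrix(truth), positions_matrix(detected))
    cand <- which(dm <= tolerance, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dm[cand])
      cand <- cand[ord, , drop = FALSE]
      used_t <- logical(nt)
      used_d <- logical(nd)
      for (r in seq_len(nrow(cand))) {
        ti <- cand[r, 1]; di <- cand[r, 2]
        if (!used_t[ti] && !used_d[di]) {
          used_t[ti] <- TRUE
          used_d[di] <- TRUE
          pairs <- rbind(pairs, data.frame(
            truth_id = truth$id[ti], detected_id = detected$id[di],
            distance = dm[ti, di]))
        }
      }
    }
  }
  m <- nrow(pairs)
  list(precision = if (nd > 0) m / nd else NA_real_,
       precision_defined = nd > 0,
       recall = if (nt > 0) m / nt else 0,
       n_matched = m, pairs = pairs)
}

pair_distances <- function(a, b) {
  # |a_i - b_j| for row vectors; small-N exact computation
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Summarize particle diameters
#'
#' @param table a particle table with a `diameter` column.
#' @return list with `mean`, `sd` (sample SD, `NA` for a single particle)
#'   and `n`.
#' @export
summarize_diameters <- function(table) {
  d <- as.data.frame(table)$diameter
  d <- d[!is.na(d)]
  if (!length(d)) stop_nanotag("no diameters to summarize")
  list(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else NA_real_,
       n = length(d))
}
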