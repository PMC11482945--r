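# Pipeline orchestration: simulate -> detect -> damp -> classify ->
# label-stats -> abundance as one configured, logged, reproducible run.

PIPELINE_SCHEMA_VERSION <- 1L
PIPELINE_STAGES <- c("simulate", "detect", "damp", "classify_sizes",
                     "label_stats", "abundance")

# 32-bit FNV-1a over the serialized config, for provenance stamping.
# Arithmetic kept in doubles below 2^53; the xor touches only the low byte.
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # multiply by the FNV prime 16777619 = 2^24 + 403, mod 2^32
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Demo pipeline configuration
#'
#' A complete configuration exercising every stage on a synthetic scene:
#' 60 tethered targets at label fraction 0.7 with a little unbound gold,
#' rendered, detected, damped, a synthetic two-population diameter sample
#' classified, labeling efficiency computed against the target truth, and
#' detected counts extrapolated to a whole-cell volume.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @return a nested list accepted by [run_pipeline()].
#' @export
demo_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(
      simulate = list(enabled = TRUE, scene = list(
        box_size = 160, voxel_size = 1.5, n_targets = 60,
        label_fraction = 0.7, offset_radius = 12.9, linker_mean = 1,
        linker_sigma = 0.5, gold_diameter = 5, gold_amplitude = 10,
        target_radius = 2, target_amplitude = 3, n_unbound_gold = 3,
        noise_sigma = 1, psf_sigma = 0, min_separation = 30,
        edge_margin = 20)),
      detect = list(enabled = TRUE, k_sigma = 4, min_voxels = 5),
      damp = list(enabled = TRUE, k = 1, side = "high-only"),
      classify_sizes = list(enabled = TRUE, source = "synthetic",
                            n_components = 2, n = 2000),
      label_stats = list(enabled = TRUE, r_offset = 12.9, tau = 5),
      abundance = list(enabled = TRUE, v_cell_um3 = 5282.5)
    )
  )
}

validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_nanotag("config must be a list or YAML path")
  if (is.null(config$seed) || !is_scalar_number(config$seed)) {
    stop_nanotag("config schema violation: integer `seed` is required")
  }
  if (is.null(config$stages) || !is.list(config$stages)) {
    stop_nanotag("config schema violation: `stages` list is required")
  }
  unknown <- setdiff(names(config$stages), PIPELINE_STAGES)
  if (length(unknown)) {
    stop_nanotag("config schema violation: unknown stage(s) ",
                 paste(unknown, collapse = ", "))
  }
  for (nm in names(config$stages)) {
    st <- config$stages[[nm]]
    if (!is.list(st) || is.null(st$enabled) || !is.logical(st$enabled)) {
      stop_nanotag("config schema violation: stage `", nm,
                   "` needs a logical `enabled`")
    }
  }
  enabled <- function(nm) isTRUE(config$stages[[nm]]$enabled)
  if (enabled("simulate") && is.null(config$stages$simulate$scene)) {
    stop_nanotag("config schema violation: simulate stage needs `scene`")
  }
  if (enabled("label_stats")) {
    ls <- config$stages$label_stats
    if (!is_scalar_number(ls$tau) || ls$tau <= 0) {
      stop_nanotag("config schema violation: label_stats needs `tau` > 0 ",
                   "(no default threshold)")
    }
    if (!is_scalar_number(ls$r_offset) || ls$r_offset < 0) {
      stop_nanotag("config schema violation: label_stats needs `r_offset` >= 0")
    }
  }
  if (enabled("abundance") &&
      !is_scalar_number(config$stages$abundance$v_cell_um3)) {
    stop_nanotag("config schema violation: abundance needs `v_cell_um3`")
  }
  for (dep in c("detect", "damp", "label_stats")) {
    if (enabled(dep) && !enabled("simulate")) {
      stop_nanotag("config schema violation: stage `", dep,
                   "` needs the simulate stage enabled")
    }
  }
  config
}

scene_spec_from_config <- function(sc, seed) {
  tether <- tether_model(
    offset_radius = sc$offset_radius %||% 12.9,
    linker_mean = sc$linker_mean %||% 0,
    linker_sigma = sc$linker_sigma %||% 0)
  scene_spec(
    box_size = sc$box_size, voxel_size = sc$voxel_size,
    n_targets = sc$n_targets, label_fraction = sc$label_fraction,
    tether = tether,
    gold_diameter = sc$gold_diameter %||% 5,
    gold_amplitude = sc$gold_amplitude %||% 10,
    target_radius = sc$target_radius %||% 5,
    target_amplitude = sc$target_amplitude %||% 3,
    n_unbound_gold = sc$n_unbound_gold %||% 0,
    noise_sigma = sc$noise_sigma %||% 0,
    psf_sigma = sc$psf_sigma %||% 0,
    min_separation = sc$min_separation %||% 0,
    edge_margin = sc$edge_margin %||% 0,
    seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the quantification pipeline
#'
#' Validates the configuration against the stage schema (before any stage
#' runs), executes the enabled stages in order, and aggregates per-stage
#' summaries into a versioned report stamped with the config hash, the seed
#' and the package version. A single global seed is fanned out to
#' deterministic per-stage seeds, so reruns of the same config are
#' byte-identical. A stage failure aborts with the stage name; artifacts
#' already written are preserved.
#'
#' @param config nested list or path to a YAML file; see
#'   [demo_pipeline_config()] for the schema by example. A config with all
#'   stages disabled yields an empty report.
#' @param output_dir optional directory; when given, truth tables and
#'   detections (CSV), the rendered volume (MRC) and the report (JSON) are
#'   written there.
#' @return the report, an S3 list of class `pipeline_report`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config <- validate_pipeline_config(config)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  report <- list(
    schema_version = PIPELINE_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("nanotag")),
    seed = as.integer(config$seed),
    config_hash = fnv1a32(as.character(cfg_json)),
    stages = list()
  )
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  enabled <- function(nm) isTRUE(config$stages[[nm]]$enabled)
  run_stage <- function(nm, expr) {
    tryCatch(expr, error = function(e) {
      stop_nanotag("pipeline stage `", nm, "` failed: ", conditionMessage(e))
    })
  }

  scene <- NULL
  vol <- NULL
  detections <- NULL

  if (enabled("simulate")) {
    run_stage("simulate", {
      spec <- scene_spec_from_config(config$stages$simulate$scene,
                                     derive_seed(config$seed, 1L))
      scene <- generate_labeled_scene(spec)
      vol <- render_volume(scene)
      report$stages$simulate <- list(
        n_targets = nrow(scene$targets),
        n_gold_bound = sum(scene$golds$bound %in% TRUE),
        n_gold_unbound = sum(scene$golds$bound %in% FALSE),
        box_nm = spec$box_size * spec$voxel_size,
        seed = spec$seed)
      if (!is.null(output_dir)) {
        write_particle_table(scene$targets,
                             file.path(output_dir, "truth_targets.csv"))
        write_particle_table(scene$golds,
                             file.path(output_dir, "truth_golds.csv"))
        write_volume(vol, file.path(output_dir, "scene.mrc"))
      }
    })
  }

  if (enabled("detect")) {
    run_stage("detect", {
      dp <- detection_params(
        k_sigma = config$stages$detect$k_sigma %||% 4,
        min_voxels = config$stages$detect$min_voxels %||% 5)
      detections <- detect_particles(vol, dp)
      ds <- if (nrow(detections)) summarize_diameters(detections) else NULL
      report$stages$detect <- list(
        n_detected = nrow(detections),
        mean_diameter_nm = if (is.null(ds)) NA else ds$mean,
        k_sigma = dp$k_sigma, min_voxels = dp$min_voxels)
      if (!is.null(output_dir)) {
        write_particle_table(detections,
                             file.path(output_dir, "detections.csv"))
      }
    })
  }

  if (enabled("damp")) {
    run_stage("damp", {
      pars <- damping_params(
        k = config$stages$damp$k %||% 1,
        side = config$stages$damp$side %||% "high-only",
        seed = derive_seed(config$seed, 3L))
      damped <- damp_high_intensity(vol, pars)
      report$stages$damp <- list(
        n_replaced = sum(damped$mask),
        fraction_replaced = mean(damped$mask), k = pars$k, side = pars$side)
      if (!is.null(output_dir)) {
        write_volume(damped$volume, file.path(output_dir, "scene_damped.mrc"))
      }
    })
  }

  if (enabled("classify_sizes")) {
    run_stage("classify_sizes", {
      cs <- config$stages$classify_sizes
      k <- cs$n_components %||% 2
      diams <- if (identical(cs$source %||% "synthetic", "detections")) {
        detections$diameter
      } else {
        generate_diameter_sample(diameter_sample_spec(
          n = cs$n %||% 2000, seed = derive_seed(config$seed, 4L)))$diameter
      }
      model <- fit_diameter_mixture(diams, n_components = k)
      report$stages$classify_sizes <- list(
        n = model$n, n_components = k,
        weights = model$weights, means_nm = model$means, sds_nm = model$sds,
        overlap = if (k == 2) class_overlap(model) else NA)
    })
  }

  if (enabled("label_stats")) {
    run_stage("label_stats", {
      ls <- config$stages$label_stats
      golds <- if (!is.null(detections) && nrow(detections)) {
        detections
      } else {
        scene$golds
      }
      res <- nearest_distances(scene$targets, golds)
      res <- correct_distances(res, ls$r_offset)
      eff <- labeling_efficiency(res, ls$tau)
      report$stages$label_stats <- list(
        n_total = eff$n_total, n_within = eff$n_within,
        percent = eff$percent, tau_nm = ls$tau, r_offset_nm = ls$r_offset,
        raw_mean_nm = eff$raw_mean, raw_sd_nm = eff$raw_sd,
        gold_source = if (!is.null(detections)) "detections" else "truth")
    })
  }

  if (enabled("abundance")) {
    run_stage("abundance", {
      ab <- config$stages$abundance
      n_det <- if (!is.null(detections)) {
        nrow(detections)
      } else if (!is.null(scene)) {
        nrow(scene$golds)
      } else {
        ab$n_detected %||%
          stop_nanotag("no detections and no `n_detected` provided")
      }
      v_imaged <- if (!is.null(vol)) {
        prod(dim(vol$grid)) * vol$voxel_size^3 * 1e-9   # nm^3 -> um^3
      } else {
        ab$v_imaged_um3 %||%
          stop_nanotag("no volume and no `v_imaged_um3` provided")
      }
      est <- extrapolate_copies(n_det, v_imaged, ab$v_cell_um3)
      report$stages$abundance <- list(
        copies_per_cell = est$copies_per_cell, se = est$se,
        n_detected = n_det, v_imaged_um3 = v_imaged,
        v_cell_um3 = ab$v_cell_um3)
    })
  }

  class(report) <- "pipeline_report"
  if (!is.null(output_dir)) {
    jsonlite::write_json(unclass(report),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> schema v%d, seed %d, config %s\n",
              x$schema_version, x$seed, x$config_hash))
  if (!length(x$stages)) {
    cat("  (no stages enabled)\n")
    return(invisible(x))
  }
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                paste(names(st), vapply(st, function(v) {
                  paste(format(v, digits = 4), collapse = ",")
                }, character(1)), sep = "=", collapse = " ")))
  }
  invisible(x)
}
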