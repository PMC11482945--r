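# Particle tables: one row per detected or ground-truth particle, positions
# in nm. Canonical columns (others are preserved but not interpreted):
#   id, x, y, z, diameter, peak_intensity, class_label, bound, parent_id

PT_COORDS <- c("x", "y", "z")
PT_KNOWN <- c("id", PT_COORDS, "diameter", "peak_intensity",
              "class_label", "bound", "parent_id")

#' Construct a particle table
#'
#' Builds the canonical particle `data.frame` used throughout the package:
#' one row per particle with positions in nm and optional per-particle
#' attributes. 2-D data use `z = 0`.
#'
#' @param x,y,z numeric position vectors in nm.
#' @param id unique particle ids (default `seq_along(x)`).
#' @param diameter,peak_intensity,class_label,bound,parent_id optional
#'   per-particle columns (`NA` where unknown).
#' @return a `data.frame` with class `particle_table` prepended.
#' @examples
#' particle_table(x = c(0, 10), y = c(0, 0), z = c(0, 5), diameter = c(5, 5))
#' @export
particle_table <- function(x = numeric(), y = numeric(), z = numeric(length(x)),
                           id = seq_along(x), diameter = NA_real_,
                           peak_intensity = NA_real_, class_label = NA_integer_,
                           bound = NA, parent_id = NA_integer_) {
  n <- length(x)
  if (length(y) == 1L) y <- rep(y, n)
  if (length(z) == 1L && n != 1L) z <- rep(z, n)
  stopifnot(length(y) == n, length(z) == n, length(id) == n)
  df <- data.frame(
    id = as.integer(id),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    diameter = rep_len(as.numeric(diameter), n),
    peak_intensity = rep_len(as.numeric(peak_intensity), n),
    class_label = rep_len(as.integer(class_label), n),
    bound = rep_len(as.logical(bound), n),
    parent_id = rep_len(as.integer(parent_id), n)
  )
  validate_particle_table(df)
}

validate_particle_table <- function(df) {
  miss <- setdiff(PT_COORDS[1:2], names(df))
  if (length(miss)) {
    stop_nanotag("particle table lacks coordinate column(s): ",
                 paste(miss, collapse = ", "))
  }
  if (!"z" %in% names(df)) df$z <- 0
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  pos <- as.matrix(df[, PT_COORDS])
  if (nrow(df) && !all(is.finite(pos))) {
    stop_nanotag("particle positions must be finite")
  }
  if (anyDuplicated(df$id)) stop_nanotag("particle ids must be unique")
  if ("diameter" %in% names(df) &&
      any(!is.na(df$diameter) & df$diameter <= 0)) {
    stop_nanotag("particle diameters must be > 0")
  }
  # canonical column types survive file round trips even when all-NA
  for (col in c("diameter", "peak_intensity")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("class_label", "parent_id")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  if ("bound" %in% names(df)) df$bound <- as.logical(df$bound)
  class(df) <- unique(c("particle_table", class(df)))
  df
}

positions_matrix <- function(table) {
  as.matrix(as.data.frame(table)[, PT_COORDS, drop = FALSE])
}

#' Read a particle table (CSV or minimal STAR)
#'
#' Positions in files may be expressed in nm (canonical), Angstrom, or voxel
#' units; the unit is declared, never inferred. CSV files default to nm with
#' a warning if no `unit` is given; STAR files declare the unit in a
#' `# coordinate_unit:` comment (and `# voxel_size_nm:` when in voxels),
#' which an explicit `unit`/`voxel_size` argument overrides.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"star"`.
#' @param unit `"nm"`, `"angstrom"` or `"voxel"`; `NULL` means take it from
#'   the file (STAR) or default to nm with a warning (CSV).
#' @param voxel_size nm per voxel, required when the unit is `"voxel"` and
#'   the file does not declare it.
#' @return a `particle_table` with positions in nm.
#' @export
read_particle_table <- function(path, dialect = c("csv", "star"),
                                unit = NULL, voxel_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_nanotag("no such file: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(unit)) {
      warning("no coordinate unit declared for CSV; assuming nm",
              call. = FALSE)
      unit <- "nm"
    }
  } else {
    parsed <- parse_star(path)
    df <- parsed$table
    if (is.null(unit)) unit <- parsed$unit
    if (is.null(voxel_size)) voxel_size <- parsed$voxel_size
    if (is.null(unit)) {
      warning("no coordinate unit declared in STAR file; assuming nm",
              call. = FALSE)
      unit <- "nm"
    }
  }
  unknown <- setdiff(names(df), PT_KNOWN)
  if (length(unknown)) {
    warning("unknown column(s) preserved: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  df <- convert_units_to_nm(df, unit, voxel_size)
  validate_particle_table(df)
}

convert_units_to_nm <- function(df, unit, voxel_size) {
  unit <- match.arg(unit, c("nm", "angstrom", "voxel"))
  factor <- switch(unit,
    nm = 1,
    angstrom = 0.1,
    voxel = {
      if (is.null(voxel_size)) {
        stop_nanotag("voxel-unit coordinates need a voxel size (nm)")
      }
      as.numeric(voxel_size)
    })
  for (col in intersect(PT_COORDS, names(df))) {
    df[[col]] <- df[[col]] * factor
  }
  df
}

#' Write a particle table (CSV or minimal STAR)
#'
#' @param table a `particle_table` (or plain data.frame with x/y columns),
#'   positions in nm.
#' @param path output file.
#' @param dialect `"csv"` or `"star"`.
#' @param unit unit to write coordinates in; `"voxel"` requires
#'   `voxel_size`. The unit is recorded in the file for STAR.
#' @param voxel_size nm per voxel for `unit = "voxel"`.
#' @return `path`, invisibly.
#' @rdname read_particle_table
#' @export
write_particle_table <- function(table, path, dialect = c("csv", "star"),
                                 unit = "nm", voxel_size = NULL) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(validate_particle_table(as.data.frame(table)))
  unit <- match.arg(unit, c("nm", "angstrom", "voxel"))
  inv <- switch(unit, nm = 1, angstrom = 10,
                voxel = {
                  if (is.null(voxel_size)) {
                    stop_nanotag("writing voxel units needs `voxel_size`")
                  }
                  1 / as.numeric(voxel_size)
                })
  for (col in intersect(PT_COORDS, names(df))) df[[col]] <- df[[col]] * inv
  if (dialect == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    write_star(df, path, unit, voxel_size)
  }
  invisible(path)
}

# --- minimal STAR dialect: one data block, one loop_, coordinate columns
# named _rlnCoordinateX/Y/Z, other canonical columns as _nano<Field>.

star_col_names <- function(cols) {
  map <- c(x = "_rlnCoordinateX", y = "_rlnCoordinateY", z = "_rlnCoordinateZ",
           id = "_nanoId", diameter = "_nanoDiameter",
           peak_intensity = "_nanoPeakIntensity",
           class_label = "_nanoClassLabel", bound = "_nanoBound",
           parent_id = "_nanoParentId")
  ifelse(cols %in% names(map), map[cols], paste0("_nano", cols))
}

write_star <- function(df, path, unit, voxel_size) {
  lines <- c(
    paste0("# coordinate_unit: ", unit),
    if (identical(unit, "voxel")) paste0("# voxel_size_nm: ",
                                         format(voxel_size, digits = 15)),
    "",
    "data_particles",
    "",
    "loop_",
    sprintf("%s #%d", star_col_names(names(df)), seq_along(df))
  )
  body <- if (nrow(df)) {
    do.call(paste, c(lapply(df, function(col) {
      if (is.logical(col)) as.integer(col)
      else if (is.numeric(col)) format(col, digits = 15, trim = TRUE)
      else as.character(col)
    }), sep = " "))
  } else character()
  writeLines(c(lines, body), path)
}

parse_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  unit <- NULL
  voxel_size <- NULL
  m <- grep("^#\\s*coordinate_unit:", lines, value = TRUE)
  if (length(m)) unit <- trimws(sub("^#\\s*coordinate_unit:", "", m[1]))
  m <- grep("^#\\s*voxel_size_nm:", lines, value = TRUE)
  if (length(m)) {
    voxel_size <- as.numeric(trimws(sub("^#\\s*voxel_size_nm:", "", m[1])))
  }
  loop_at <- grep("^\\s*loop_\\s*$", lines)
  if (!length(loop_at)) stop_nanotag("malformed STAR file: no loop_ block")
  rest <- lines[(loop_at[1] + 1L):length(lines)]
  tag_idx <- grep("^\\s*_", rest)
  if (!length(tag_idx)) stop_nanotag("malformed STAR file: no loop columns")
  tags <- sub("\\s*#\\d+\\s*$", "", trimws(rest[tag_idx]))
  body <- rest[setdiff(seq_along(rest), tag_idx)]
  body <- trimws(body)
  body <- body[nzchar(body) & !startsWith(body, "#")]
  cols <- star_to_canonical(tags)
  if (!all(c("x", "y") %in% cols)) {
    stop_nanotag("STAR file lacks coordinate columns")
  }
  if (!length(body)) {
    df <- as.data.frame(setNames(rep(list(numeric()), length(cols)), cols))
  } else {
    parts <- strsplit(body, "\\s+")
    if (any(lengths(parts) != length(cols))) {
      stop_nanotag("malformed STAR row: field count mismatch")
    }
    mat <- do.call(rbind, parts)
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- cols
    for (col in names(df)) {
      suppressWarnings(num <- as.numeric(df[[col]]))
      if (!anyNA(num) || all(is.na(df[[col]]) | df[[col]] == "NA")) {
        df[[col]] <- num
      }
    }
    if ("bound" %in% names(df)) df$bound <- as.logical(df$bound)
  }
  list(table = df, unit = unit, voxel_size = voxel_size)
}

star_to_canonical <- function(tags) {
  map <- c(`_rlnCoordinateX` = "x", `_rlnCoordinateY` = "y",
           `_rlnCoordinateZ` = "z", `_nanoId` = "id",
           `_nanoDiameter` = "diameter",
           `_nanoPeakIntensity` = "peak_intensity",
           `_nanoClassLabel` = "class_label", `_nanoBound` = "bound",
           `_nanoParentId` = "parent_id")
  ifelse(tags %in% names(map), map[tags], sub("^_nano", "", tags))
}
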