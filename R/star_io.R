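#' Particle metadata tables
#'
#' A `particle_table` is a tibble with one row per picked particle and at
#' least the columns `particle_id` (unique string), `tomogram_id` (string),
#' `x`, `y`, `z` (0-based voxel coordinates at the table's binning) and
#' `pixel_size_A` (angstrom per voxel). Optional derived columns are
#' `depth_nm` (shortest distance to the nearer milling surface),
#' `thickness_nm` (local lamella thickness), `backside_um` (distance to the
#' backside amorphous boundary) and `cohort_label`. Physical distances are
#' always `voxels * pixel_size_A`, so tables must state the binned pixel
#' size (e.g. 15.2 A/px for binning-8 tomograms).
#'
#' @param df data frame with at least `tomogram_id`, `x`, `y`, `z`.
#' @param pixel_size_A pixel size in angstrom per voxel, used when `df` has
#'   no `pixel_size_A` column.
#' @return a tibble of class `particle_table`.
#' @export
particle_table <- function(df, pixel_size_A = NULL) {
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) abort_fib("particle table is empty", "fib_empty_input")
  if (!"particle_id" %in% names(df)) {
    df$particle_id <- sprintf("P%06d", seq_len(nrow(df)))
  }
  df$particle_id <- as.character(df$particle_id)
  if (!"pixel_size_A" %in% names(df)) {
    if (is.null(pixel_size_A)) {
      abort_fib("pixel_size_A missing: supply a column or an argument",
                "fib_format_error")
    }
    df$pixel_size_A <- pixel_size_A
  }
  validate_particle_table(df)
  front <- intersect(
    c("particle_id", "tomogram_id", "x", "y", "z", "pixel_size_A",
      "depth_nm", "thickness_nm", "backside_um", "cohort_label"),
    names(df))
  df <- df[, c(front, setdiff(names(df), front))]
  class(df) <- unique(c("particle_table", class(df)))
  df
}

validate_particle_table <- function(df) {
  for (col in c("tomogram_id", "x", "y", "z", "pixel_size_A")) {
    if (!col %in% names(df)) {
      abort_fib(sprintf("missing required column '%s'", col),
                "fib_format_error")
    }
  }
  if (anyDuplicated(df$particle_id)) {
    abort_fib("particle_id values are not unique", "fib_format_error")
  }
  if (any(!nzchar(df$tomogram_id) | is.na(df$tomogram_id))) {
    abort_fib("tomogram_id must be non-empty", "fib_format_error")
  }
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort_fib("particle coordinates must be finite", "fib_format_error")
  }
  if (!all(is.finite(df$pixel_size_A)) || any(df$pixel_size_A <= 0)) {
    abort_fib("pixel_size_A must be positive", "fib_format_error")
  }
  invisible(df)
}

# Column name mapping between the STAR dialect and the internal table.
.star_map <- c(
  rlnImageName          = "particle_id",
  rlnTomoName           = "tomogram_id",
  rlnCoordinateX        = "x",
  rlnCoordinateY        = "y",
  rlnCoordinateZ        = "z",
  rlnDetectorPixelSize  = "pixel_size_A",
  fibDepthNm            = "depth_nm",
  fibThicknessNm        = "thickness_nm",
  fibBacksideUm         = "backside_um",
  fibCohort             = "cohort_label",
  fibTrueDepthNm        = "true_depth_nm",
  fibAcquisitionUm      = "acquisition_um"
)

# Parse every loop block of a STAR file into a named list of data frames.
# Accepts both RELION-3.1 named blocks (data_particles) and legacy bare
# data_ blocks; column labels are matched case-sensitively.
parse_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  blocks <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (startsWith(lines[i], "data_")) {
      block_name <- sub("^data_", "", lines[i])
      i <- i + 1L
      while (i <= n && lines[i] != "loop_" && !startsWith(lines[i], "data_")) {
        i <- i + 1L
      }
      if (i <= n && lines[i] == "loop_") {
        i <- i + 1L
        labels <- character()
        while (i <= n && startsWith(lines[i], "_")) {
          labels <- c(labels, sub("^_([^ \t]+).*$", "\\1", lines[i]))
          i <- i + 1L
        }
        rows <- list()
        while (i <= n && nzchar(lines[i]) && !startsWith(lines[i], "data_")) {
          fields <- strsplit(lines[i], "[ \t]+")[[1]]
          if (length(fields) != length(labels)) {
            abort_fib(sprintf(
              "malformed STAR row in block 'data_%s': %d fields for %d columns",
              block_name, length(fields), length(labels)), "fib_format_error")
          }
          rows[[length(rows) + 1L]] <- fields
          i <- i + 1L
        }
        if (length(rows)) {
          m <- do.call(rbind, rows)
          df <- as.data.frame(m, stringsAsFactors = FALSE)
          names(df) <- labels
          for (j in seq_along(df)) {
            conv <- suppressWarnings(as.numeric(df[[j]]))
            if (!anyNA(conv)) df[[j]] <- conv
          }
        } else {
          df <- as.data.frame(matrix(character(), ncol = length(labels),
                                     dimnames = list(NULL, labels)))
        }
        blocks[[if (nzchar(block_name)) block_name else "unnamed"]] <- df
      }
    } else {
      i <- i + 1L
    }
  }
  blocks
}

#' Read a particle STAR file
#'
#' Reads a RELION/Warp-style STAR particle table. Both named
#' `data_particles` blocks and legacy bare `data_` blocks are accepted;
#' unknown columns are preserved opaquely under their STAR labels.
#'
#' @param path path to a STAR file.
#' @param required_columns STAR labels that must be present; defaults to the
#'   three coordinate columns plus a tomogram/micrograph name.
#' @param pixel_size_A fallback pixel size (A/voxel) when the table has no
#'   `rlnDetectorPixelSize` column.
#' @return a [particle_table()].
#' @export
read_particle_star <- function(path,
                               required_columns = c("rlnCoordinateX",
                                                    "rlnCoordinateY",
                                                    "rlnCoordinateZ"),
                               pixel_size_A = NULL) {
  if (!file.exists(path)) {
    abort_fib(sprintf("file not found: %s", path), "fib_io_error")
  }
  blocks <- parse_star(path)
  has_coords <- vapply(blocks, function(b) "rlnCoordinateX" %in% names(b),
                       logical(1))
  if (!any(has_coords)) {
    abort_fib("no particle data block with coordinate columns found",
              "fib_format_error")
  }
  pref <- which(names(blocks) == "particles" & has_coords)
  df <- blocks[[if (length(pref)) pref[1] else which(has_coords)[1]]]
  if (nrow(df) == 0) abort_fib("particle table is empty", "fib_empty_input")
  missing <- setdiff(required_columns, names(df))
  if (length(missing)) {
    abort_fib(sprintf("missing required column '%s'", missing[1]),
              "fib_format_error")
  }
  if (!"rlnTomoName" %in% names(df) && "rlnMicrographName" %in% names(df)) {
    names(df)[names(df) == "rlnMicrographName"] <- "rlnTomoName"
  }
  if (!"rlnTomoName" %in% names(df)) {
    abort_fib("missing required column 'rlnTomoName' (or 'rlnMicrographName')",
              "fib_format_error")
  }
  known <- names(df) %in% names(.star_map)
  names(df)[known] <- .star_map[names(df)[known]]
  particle_table(df, pixel_size_A = pixel_size_A)
}

#' Write a particle table to STAR
#'
#' Emits a single `data_particles` loop block. Derived columns
#' (`depth_nm`, `thickness_nm`, `backside_um`, `cohort_label`) are written
#' as additional named columns (`_fibDepthNm`, ...); opaque columns are
#' written back under their own labels.
#'
#' @param table a [particle_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_particle_star <- function(table, path) {
  if (!inherits(table, "particle_table")) table <- particle_table(table)
  if (nrow(table) == 0) abort_fib("particle table is empty", "fib_empty_input")
  inv_map <- setNames(names(.star_map), .star_map)
  df <- as.data.frame(table)
  keep <- !vapply(df, function(col) all(is.na(col)), logical(1))
  df <- df[, keep, drop = FALSE]
  labels <- ifelse(names(df) %in% names(inv_map), inv_map[names(df)], names(df))
  fmt_col <- function(col) {
    if (is.numeric(col)) sprintf("%.10g", col) else as.character(col)
  }
  body <- do.call(cbind, lapply(df, fmt_col))
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort_fib(
                    sprintf("cannot open '%s' for writing", path),
                    "fib_io_error"))
  on.exit(close(con))
  writeLines(c("", "data_particles", "", "loop_",
               sprintf("_%s #%d", labels, seq_along(labels))), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
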