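#' Interpolate sparse surface annotations into a boundary sheet
#'
#' Builds a continuous height field h(u, s) for one milling surface of one
#' tomogram from annotations on a sparse subset of slices: linear
#' interpolation along each annotated polyline, linear blending between
#' adjacent annotated slices, and nearest-slice clamping beyond the first
#' and last annotated slice. The resulting regular grid is triangulated
#' (two facets per cell) for shortest-distance queries.
#'
#' @param annotations an [annotation_set()] subset holding exactly one
#'   tomogram and one sheet, or a data frame with `slice_index`, `point_u`,
#'   `point_v` columns.
#' @param grid_step lateral grid step in voxels (default 10).
#' @param role sheet role, `"front"` or `"back"`; taken from the
#'   annotations when present.
#' @return an object of class `surface_sheet` with fields `u`, `s`
#'   (lateral grid coordinates, voxels), `h` (height matrix, voxels),
#'   `grid_step` and `role`.
#' @export
interpolate_surface <- function(annotations, grid_step = 10, role = NULL) {
  ann <- tibble::as_tibble(annotations)
  if (nrow(ann) == 0) abort_fib("empty annotation", "fib_empty_input")
  if ("sheet" %in% names(ann)) {
    if (length(unique(ann$sheet)) > 1) {
      abort_fib("annotations span more than one sheet", "fib_format_error")
    }
    role <- role %||% ann$sheet[1]
  }
  role <- role %||% "front"
  slices <- split(ann, ann$slice_index)
  s_pos <- sort(as.numeric(names(slices)))
  npts <- vapply(slices, nrow, integer(1))
  if (any(npts < 2)) {
    abort_fib("each annotated slice needs at least 2 points",
              "fib_format_error")
  }
  u_min <- min(ann$point_u); u_max <- max(ann$point_u)
  if (u_max <= u_min) {
    abort_fib("annotated points have zero lateral extent", "fib_format_error")
  }
  u_grid <- seq(u_min, u_max, by = grid_step)
  if (u_grid[length(u_grid)] < u_max) u_grid <- c(u_grid, u_max)
  # heights per annotated slice on the shared u grid (polyline interpolation,
  # constant extrapolation at the ends of each polyline)
  slice_h <- vapply(as.character(s_pos), function(key) {
    sl <- slices[[key]]
    ord <- order(sl$point_u)
    approx(sl$point_u[ord], sl$point_v[ord], xout = u_grid, rule = 2,
           ties = mean)$y
  }, numeric(length(u_grid)))
  slice_h <- matrix(slice_h, nrow = length(u_grid))
  if (length(s_pos) == 1) {
    s_grid <- s_pos + c(-grid_step, 0, grid_step)  # constant extrusion
    h <- slice_h[, c(1, 1, 1), drop = FALSE]
  } else {
    s_grid <- seq(min(s_pos), max(s_pos), by = grid_step)
    if (s_grid[length(s_grid)] < max(s_pos)) s_grid <- c(s_grid, max(s_pos))
    h <- t(apply(slice_h, 1, function(hu) {
      approx(s_pos, hu, xout = s_grid, rule = 2)$y
    }))
  }
  structure(list(u = u_grid, s = s_grid, h = h,
                 grid_step = grid_step, role = role),
            class = "surface_sheet")
}

#' @export
print.surface_sheet <- function(x, ...) {
  cat(sprintf("<surface_sheet '%s', %d x %d grid, step %g voxels>\n",
              x$role, length(x$u), length(x$s), x$grid_step))
  invisible(x)
}

# Bilinear interpolation of a sheet's height field at lateral positions
# (x, y); positions outside the grid return NA.
sheet_height <- function(sheet, x, y) {
  u <- sheet$u; s <- sheet$s; h <- sheet$h
  iu <- findInterval(x, u, rightmost.closed = TRUE)
  is_ <- findInterval(y, s, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(x))
  ok <- iu >= 1 & iu < length(u) & is_ >= 1 & is_ < length(s) &
    x >= u[1] & x <= u[length(u)] & y >= s[1] & y <= s[length(s)]
  if (!any(ok)) return(out)
  iu <- pmin(iu[ok], length(u) - 1L); is_ <- pmin(is_[ok], length(s) - 1L)
  fx <- (x[ok] - u[iu]) / (u[iu + 1L] - u[iu])
  fy <- (y[ok] - s[is_]) / (s[is_ + 1L] - s[is_])
  out[ok] <- h[cbind(iu, is_)] * (1 - fx) * (1 - fy) +
    h[cbind(iu + 1L, is_)] * fx * (1 - fy) +
    h[cbind(iu, is_ + 1L)] * (1 - fx) * fy +
    h[cbind(iu + 1L, is_ + 1L)] * fx * fy
  out
}

#' Per-particle shortest distance to the milling surfaces
#'
#' For each particle, the unsigned 3-D shortest (point-to-triangle)
#' distance to the nearer of the two interpolated boundary sheets, plus the
#' local lamella thickness at the particle's lateral position and a flag
#' for whether the particle lies between the sheets. Distances are
#' converted to nanometres (`voxels * pixel_size_A / 10`). Particles
#' laterally outside the sheets' grids are flagged (`NA` depth) and their
#' count reported via a message.
#'
#' @param particles a [particle_table()] (or data frame with `particle_id`,
#'   `x`, `y`, `z`).
#' @param front_sheet,back_sheet [interpolate_surface()] results for the
#'   two milling surfaces.
#' @param pixel_size_A pixel size (A/voxel); default taken from the table.
#' @return tibble with `particle_id`, `depth_nm`, `thickness_nm`, `inside`.
#' @export
particle_depth <- function(particles, front_sheet, back_sheet,
                           pixel_size_A = NULL) {
  stopifnot(inherits(front_sheet, "surface_sheet"),
            inherits(back_sheet, "surface_sheet"))
  df <- tibble::as_tibble(particles)
  pixel_size_A <- pixel_size_A %||% df$pixel_size_A[1]
  if (!is_scalar_number(pixel_size_A) || pixel_size_A <= 0) {
    abort_fib("pixel_size_A must be positive", "fib_format_error")
  }
  P <- cbind(df$x, df$y, df$z)
  hf <- sheet_height(front_sheet, df$x, df$y)
  hb <- sheet_height(back_sheet, df$x, df$y)
  lateral_ok <- !is.na(hf) & !is.na(hb)
  d_front <- cpp_grid_surface_dist(P, front_sheet$u, front_sheet$s,
                                   front_sheet$h)
  d_back <- cpp_grid_surface_dist(P, back_sheet$u, back_sheet$s,
                                  back_sheet$h)
  nm <- pixel_size_A / 10
  depth_nm <- pmin(d_front, d_back) * nm
  lo <- pmin(hf, hb); hi <- pmax(hf, hb)
  inside <- lateral_ok & df$z >= lo & df$z <= hi
  thickness_nm <- (hi - lo) * nm
  depth_nm[!lateral_ok] <- NA_real_
  thickness_nm[!lateral_ok] <- NA_real_
  inside[!lateral_ok] <- NA
  n_out <- sum(!lateral_ok)
  if (n_out > 0) {
    message(sprintf("%d particle(s) laterally outside the surface grids %s",
                    n_out, "were flagged (depth_nm = NA)"))
  }
  tibble::tibble(particle_id = as.character(df$particle_id),
                 depth_nm = depth_nm, thickness_nm = thickness_nm,
                 inside = inside)
}

#' Local lamella thickness
#'
#' Vertical separation of the two boundary height fields at given lateral
#' positions, in nanometres. Positions where the back sheet lies below the
#' front sheet (crossing sheets) are flagged.
#'
#' @param front_sheet,back_sheet surface sheets.
#' @param lateral_position matrix or data frame of lateral positions
#'   (columns `x`/`u` and `y`/`s`, voxels).
#' @param pixel_size_A pixel size in A/voxel.
#' @return tibble with `thickness_nm` and logical `crossed`.
#' @export
local_thickness <- function(front_sheet, back_sheet, lateral_position,
                            pixel_size_A) {
  lp <- as.data.frame(lateral_position)
  names(lp)[1:2] <- c("x", "y")
  hf <- sheet_height(front_sheet, lp$x, lp$y)
  hb <- sheet_height(back_sheet, lp$x, lp$y)
  sep <- (hb - hf) * pixel_size_A / 10
  crossed <- !is.na(sep) & sep < 0
  tibble::tibble(thickness_nm = ifelse(crossed, NA_real_, sep),
                 crossed = crossed)
}

#' Dataset-level thickness summary
#'
#' Summarises per-tomogram mean lamella thicknesses into a dataset mean,
#' median and sample standard deviation, the summary usually quoted for a
#' lamella preparation session.
#'
#' @param depth_records tibble with `tomogram_id` and `thickness_nm`
#'   (e.g. [particle_depth()] output joined to the particle table).
#' @return tibble with `mean_nm`, `median_nm`, `sd_nm`, `n_tomograms`,
#'   and `single_tomogram` flag (SD reported as 0 with a warning then).
#' @export
thickness_summary <- function(depth_records) {
  df <- tibble::as_tibble(depth_records)
  df <- df[!is.na(df$thickness_nm), ]
  if (nrow(df) == 0) abort_fib("no valid thickness records",
                               "fib_empty_input")
  per_tomo <- dplyr::summarise(dplyr::group_by(df, .data$tomogram_id),
                               thickness_nm = mean(.data$thickness_nm),
                               .groups = "drop")
  single <- nrow(per_tomo) == 1
  if (single) warning("single tomogram: thickness SD reported as 0")
  tibble::tibble(
    mean_nm = mean(per_tomo$thickness_nm),
    median_nm = median(per_tomo$thickness_nm),
    sd_nm = if (single) 0 else sd(per_tomo$thickness_nm),
    n_tomograms = nrow(per_tomo),
    single_tomogram = single
  )
}

#' Build boundary sheets for every tomogram in an annotation set
#'
#' @param annotations an [annotation_set()].
#' @param grid_step lateral grid step in voxels.
#' @return named list (per tomogram) of lists with `front` and `back`
#'   surface sheets.
#' @export
build_surfaces <- function(annotations, grid_step = 10) {
  stopifnot(inherits(annotations, "annotation_set"))
  per_tomo <- split(tibble::as_tibble(annotations), annotations$tomogram_id)
  lapply(per_tomo, function(ann) {
    sheets <- lapply(c(front = "front", back = "back"), function(sh) {
      sub <- ann[ann$sheet == sh, ]
      if (nrow(sub) == 0) {
        abort_fib(sprintf("tomogram '%s' lacks a '%s' sheet annotation",
                          ann$tomogram_id[1], sh), "fib_format_error")
      }
      interpolate_surface(sub, grid_step = grid_step, role = sh)
    })
    sheets
  })
}
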