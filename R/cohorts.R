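#' Cohort assignments
#'
#' A `cohort_assignment` records one particle group: its label, member
#' particle ids, per-tomogram member counts, the bin edges (half-open,
#' `[lower, upper)`) with unit, and the RNG seed (if any) that produced it.
#'
#' @keywords internal
new_cohort <- function(label, ids, tomogram_ids, lower = NA_real_,
                       upper = NA_real_, unit = NA_character_, seed = NA) {
  stopifnot(length(ids) == length(tomogram_ids))
  structure(list(
    label = label,
    particle_ids = as.character(ids),
    counts_by_tomogram = table(factor(tomogram_ids)),
    lower = lower, upper = upper, unit = unit, seed = seed
  ), class = "cohort_assignment")
}

#' @export
print.cohort_assignment <- function(x, ...) {
  cat(sprintf("<cohort '%s': %d particles in %d tomogram(s)>\n",
              x$label, length(x$particle_ids),
              sum(x$counts_by_tomogram > 0)))
  invisible(x)
}

#' @export
length.cohort_assignment <- function(x) length(x$particle_ids)

#' Assign particles to half-open depth bins
#'
#' Groups particles by shortest distance to the nearer milling surface
#' into half-open bins `[lower, upper)` of `bin_width` nm from 0 up to
#' `max_depth` nm (default 5-nm bins to 60 nm, i.e. 12 bins). Particles at
#' or beyond `max_depth`, or with missing depth, are excluded from the bins
#' and returned as the control pool.
#'
#' @param particles a [particle_table()] (or tibble) with `depth_nm` and
#'   `tomogram_id`.
#' @param bin_width bin width in nm.
#' @param max_depth maximum binned depth in nm.
#' @return list with `bins` (named list of `cohort_assignment`s, shallow to
#'   deep, empty bins dropped) and `pool` (tibble of unbinned particles
#'   with valid depth).
#' @export
assign_depth_bins <- function(particles, bin_width = 5, max_depth = 60) {
  df <- tibble::as_tibble(particles)
  if (!"depth_nm" %in% names(df)) {
    abort_fib("particles lack a depth_nm column", "fib_format_error")
  }
  if (max_depth %% bin_width != 0) {
    abort_fib("bin_width must divide max_depth", "fib_config_error")
  }
  edges <- seq(0, max_depth, by = bin_width)
  valid <- !is.na(df$depth_nm) & df$depth_nm >= 0
  binned <- valid & df$depth_nm < max_depth
  if (!any(binned)) abort_fib("no particle falls in any depth bin",
                              "fib_empty_input")
  idx <- findInterval(df$depth_nm[binned], edges)  # 1..n_bins, half-open
  labels <- sprintf("depth_%02d_%02d", edges[-length(edges)], edges[-1])
  bins <- list()
  for (b in seq_len(length(edges) - 1)) {
    sel <- which(binned)[idx == b]
    if (length(sel) == 0) next
    bins[[labels[b]]] <- new_cohort(labels[b], df$particle_id[sel],
                                    df$tomogram_id[sel],
                                    lower = edges[b], upper = edges[b + 1],
                                    unit = "nm")
  }
  pool <- df[valid & !binned, ]
  list(bins = bins, pool = pool)
}

#' Per-particle backside distance
#'
#' Distance of a particle to the backside amorphous boundary: the tilt
#' series acquisition area's distance to the boundary plus the particle's
#' signed lateral displacement from the tomogram centre along the milling
#' axis (the tomogram X axis). Negative results are flagged as `NA` and
#' excluded from binning.
#'
#' @param acquisition_distance_um distance of the acquisition area to the
#'   amorphous boundary, micrometres (>= 0).
#' @param particle_x_offset_um signed displacement of the particle from the
#'   tomogram centre along the milling axis, micrometres.
#' @return distances in micrometres (`NA` where negative).
#' @export
backside_particle_distance <- function(acquisition_distance_um,
                                       particle_x_offset_um) {
  if (any(acquisition_distance_um < 0, na.rm = TRUE)) {
    abort_fib("acquisition distance must be >= 0", "fib_format_error")
  }
  d <- acquisition_distance_um + particle_x_offset_um
  n_neg <- sum(d < 0, na.rm = TRUE)
  if (n_neg > 0) {
    message(sprintf("%d particle(s) with negative backside distance flagged",
                    n_neg))
    d[!is.na(d) & d < 0] <- NA_real_
  }
  d
}

#' Assign particles to backside-distance bins
#'
#' Half-open 1-um bins of distance to the amorphous boundary, from 0 up to
#' `max_um`.
#'
#' @param particles tibble with `backside_um` and `tomogram_id`.
#' @param bin_width bin width in micrometres.
#' @param max_um maximum binned distance in micrometres.
#' @return named list of `cohort_assignment`s.
#' @export
assign_backside_bins <- function(particles, bin_width = 1, max_um = 5) {
  df <- tibble::as_tibble(particles)
  if (!"backside_um" %in% names(df)) {
    abort_fib("particles lack a backside_um column", "fib_format_error")
  }
  edges <- seq(0, max_um, by = bin_width)
  valid <- !is.na(df$backside_um) & df$backside_um >= 0 &
    df$backside_um < max_um
  if (!any(valid)) abort_fib("no particle falls in any backside bin",
                             "fib_empty_input")
  idx <- findInterval(df$backside_um[valid], edges)
  labels <- sprintf("backside_%d_%dum", edges[-length(edges)], edges[-1])
  bins <- list()
  for (b in seq_len(length(edges) - 1)) {
    sel <- which(valid)[idx == b]
    if (length(sel) == 0) next
    bins[[labels[b]]] <- new_cohort(labels[b], df$particle_id[sel],
                                    df$tomogram_id[sel],
                                    lower = edges[b], upper = edges[b + 1],
                                    unit = "um")
  }
  bins
}

#' Draw a tomogram-matched random control for a depth group
#'
#' For each tomogram represented in the group, draws without replacement
#' the same number of particles from the eligible pool (particles with
#' depth strictly greater than `eligibility_floor_nm`) in that tomogram.
#' Where the eligible pool is short, all available particles are taken and
#' the excess group members in that tomogram are removed at random so the
#' group and its control have identical per-tomogram counts. If the floor
#' empties the pool for a tomogram, it is relaxed to the group's upper bin
#' edge for that tomogram with a warning; tomograms with no eligible pool
#' at all have their group members dropped (logged).
#'
#' @param group a `cohort_assignment` (from [assign_depth_bins()]).
#' @param pool tibble of candidate control particles with `particle_id`,
#'   `tomogram_id`, `depth_nm`.
#' @param eligibility_floor_nm minimum control depth, nm; default 60
#'   (the deepest studied bin, so controls lie outside the damage range).
#' @param seed RNG seed; the draw is fully determined by it.
#' @return list with `control` (a `cohort_assignment`) and `group` (the
#'   possibly downsampled input group).
#' @export
draw_matched_control <- function(group, pool, eligibility_floor_nm = 60,
                                 seed = 1) {
  stopifnot(inherits(group, "cohort_assignment"))
  pool <- tibble::as_tibble(pool)
  counts <- group$counts_by_tomogram
  counts <- counts[counts > 0]
  tomos <- sort(names(counts))
  ctrl_ids <- character(); ctrl_tomo <- character()
  keep_ids <- character(); keep_tomo <- character()
  group_tomo <- rep(names(group$counts_by_tomogram),
                    group$counts_by_tomogram)
  # reconstruct per-tomogram member id lists in a stable order
  ord <- order(group_tomo, group$particle_ids)
  seeds <- derive_seeds(seed, length(tomos))
  for (k in seq_along(tomos)) {
    tm <- tomos[k]
    g_ids <- sort(group$particle_ids[group_tomo == tm])
    elig <- pool[pool$tomogram_id == tm &
                   !is.na(pool$depth_nm) &
                   pool$depth_nm > eligibility_floor_nm, ]
    if (nrow(elig) == 0 && is.finite(group$upper)) {
      elig <- pool[pool$tomogram_id == tm &
                     !is.na(pool$depth_nm) &
                     pool$depth_nm > group$upper, ]
      if (nrow(elig) > 0) {
        warning(sprintf(
          "tomogram '%s': eligibility floor relaxed to the bin edge (%g nm)",
          tm, group$upper))
      }
    }
    if (nrow(elig) == 0) {
      message(sprintf(
        "tomogram '%s': no eligible control pool; %d group particle(s) dropped",
        tm, length(g_ids)))
      next
    }
    n_take <- min(length(g_ids), nrow(elig))
    elig <- elig[order(elig$particle_id), ]
    drawn <- with_seed(seeds[k], {
      pick <- sample.int(nrow(elig), n_take)
      kept <- if (n_take < length(g_ids)) sort(sample(g_ids, n_take)) else g_ids
      list(ctrl = elig$particle_id[pick], kept = kept)
    })
    ctrl_ids <- c(ctrl_ids, drawn$ctrl)
    ctrl_tomo <- c(ctrl_tomo, rep(tm, n_take))
    keep_ids <- c(keep_ids, drawn$kept)
    keep_tomo <- c(keep_tomo, rep(tm, n_take))
  }
  if (length(ctrl_ids) == 0) {
    abort_fib(sprintf("no control could be drawn for group '%s'",
                      group$label), "fib_empty_input")
  }
  control <- new_cohort(paste0(group$label, "_control"), ctrl_ids, ctrl_tomo,
                        lower = eligibility_floor_nm, upper = Inf,
                        unit = group$unit, seed = seed)
  group_out <- new_cohort(group$label, keep_ids, keep_tomo,
                          lower = group$lower, upper = group$upper,
                          unit = group$unit, seed = seed)
  list(group = group_out, control = control)
}

#' Split particles into threshold comparison sets
#'
#' Draws three seeded uniform random samples of exactly `n` particles:
#' from all particles with valid depth, from those shallower than
#' `threshold` nm, and from those at or beyond it. Samples are drawn
#' without replacement within each stratum.
#'
#' @param particles tibble with `particle_id`, `tomogram_id`, `depth_nm`.
#' @param threshold depth threshold in nm (default 30).
#' @param n sample size per set (default 10000).
#' @param seed RNG seed.
#' @return named list of three `cohort_assignment`s: `all`, `lt_threshold`,
#'   `gt_threshold`.
#' @export
split_threshold_sets <- function(particles, threshold = 30, n = 10000,
                                 seed = 1) {
  df <- tibble::as_tibble(particles)
  df <- df[!is.na(df$depth_nm), ]
  strata <- list(
    all = df,
    lt_threshold = df[df$depth_nm < threshold, ],
    gt_threshold = df[df$depth_nm >= threshold, ]
  )
  seeds <- derive_seeds(seed, length(strata))
  out <- list()
  for (k in seq_along(strata)) {
    s <- strata[[k]]
    if (nrow(s) < n) {
      abort_fib(sprintf(
        "stratum '%s' has only %d particles (need %d)",
        names(strata)[k], nrow(s), n), "fib_insufficient_particles")
    }
    s <- s[order(s$particle_id), ]
    pick <- with_seed(seeds[k], sample.int(nrow(s), n))
    out[[names(strata)[k]]] <- new_cohort(
      names(strata)[k], s$particle_id[pick], s$tomogram_id[pick],
      lower = if (k == 2) 0 else if (k == 3) threshold else NA_real_,
      upper = if (k == 2) threshold else NA_real_,
      unit = "nm", seed = seed)
  }
  out
}
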