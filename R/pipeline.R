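.run_config_defaults <- list(
  depth_bin_width_nm = 5,
  depth_max_nm = 60,
  backside_bin_width_um = 1,
  backside_max_um = 5,
  min_particles = 400,
  repeats = 3,
  extrapolate_n = 5000,
  threshold_nm = 30,
  eligibility_floor_nm = 60,
  grid_step = 10,
  seed = 1
)

#' Validate and normalise a run configuration
#'
#' Fills defaults (5-nm depth bins to 60 nm, 1-um backside bins to 5 um,
#' 400-particle minimum, 3 repeats, extrapolation to 5000 particles,
#' 30-nm threshold, 60-nm control eligibility floor), checks consistency,
#' and errors on unknown keys. Accepts a YAML file path or a list;
#' normalisation is idempotent.
#'
#' @param config YAML path, a list of overrides, or `NULL` for defaults.
#' @return list of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort_fib(sprintf("config file not found: %s", config),
                "fib_io_error")
    }
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  config <- config[!vapply(config, is.null, logical(1))]
  unknown <- setdiff(names(config), names(.run_config_defaults))
  if (length(unknown)) {
    abort_fib(sprintf("unknown config key(s) %s; valid keys: %s",
                      paste0("'", unknown, "'", collapse = ", "),
                      paste(names(.run_config_defaults), collapse = ", ")),
              "fib_config_error")
  }
  out <- .run_config_defaults
  out[names(config)] <- config
  for (key in names(out)) {
    if (!is_scalar_number(out[[key]]) || out[[key]] <= 0) {
      abort_fib(sprintf("config key '%s' must be a positive number", key),
                "fib_config_error")
    }
  }
  if (out$depth_max_nm %% out$depth_bin_width_nm != 0) {
    abort_fib("depth_bin_width_nm must divide depth_max_nm",
              "fib_config_error")
  }
  if (out$backside_max_um %% out$backside_bin_width_um != 0) {
    abort_fib("backside_bin_width_um must divide backside_max_um",
              "fib_config_error")
  }
  class(out) <- "run_config"
  out
}

#' Resolution providers
#'
#' A resolution provider supplies the per-subset-size resolutions for a
#' particle set; the pipeline is agnostic to whether they come from
#' refinement software (pre-computed CSV) or from the synthetic generative
#' model. A provider is called as
#' `provider(label, members, sizes, n_repeats, seed)` and must return a
#' [resolution_series()].
#'
#' `synthetic_resolution_provider()` draws series from the damage model of
#' a [synthetic_config()], using the mean ground-truth depth of the set's
#' members as the set's representative depth (its `depth_nm` / backside
#' flat-field value when no `true_depth_nm` column is present).
#'
#' `csv_resolution_provider()` serves pre-computed series from a CSV with
#' columns `group`, `repeat_index`, `n_particles`, `resolution_A`.
#'
#' @param config a [synthetic_config()].
#' @return a provider function.
#' @export
synthetic_resolution_provider <- function(config) {
  force(config)
  function(label, members, sizes, n_repeats, seed) {
    depth_col <- if ("true_depth_nm" %in% names(members)) {
      members$true_depth_nm
    } else if ("depth_nm" %in% names(members)) {
      members$depth_nm
    } else {
      abort_fib("members carry no depth information", "fib_format_error")
    }
    cfg <- config
    cfg$repeats <- n_repeats
    simulate_resolution_series(mean(depth_col, na.rm = TRUE), sizes, cfg,
                               seed = seed, group = label)
  }
}

#' @rdname synthetic_resolution_provider
#' @param path CSV path of pre-computed resolutions.
#' @export
csv_resolution_provider <- function(path) {
  if (!file.exists(path)) {
    abort_fib(sprintf("resolution CSV not found: %s", path), "fib_io_error")
  }
  tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  function(label, members, sizes, n_repeats, seed) {
    sub <- tab[tab$group == label, ]
    if (nrow(sub) == 0) {
      abort_fib(sprintf("no pre-computed resolutions for group '%s'",
                        label), "fib_empty_input")
    }
    resolution_series(label, sub$repeat_index, sub$n_particles,
                      sub$resolution_A)
  }
}

# Compute depths for every particle against its tomogram's sheet pair.
add_depths <- function(particles, surfaces) {
  parts <- split(tibble::as_tibble(particles), particles$tomogram_id)
  missing <- setdiff(names(parts), names(surfaces))
  if (length(missing)) {
    abort_fib(sprintf("no surfaces for tomogram(s): %s",
                      paste(missing, collapse = ", ")), "fib_format_error")
  }
  res <- lapply(names(parts), function(tm) {
    d <- particle_depth(parts[[tm]], surfaces[[tm]]$front,
                        surfaces[[tm]]$back)
    out <- parts[[tm]]
    out$depth_nm <- d$depth_nm
    out$thickness_nm <- d$thickness_nm
    out$inside <- d$inside
    out
  })
  dplyr::bind_rows(res)
}

# Fit one cohort's B-factor through a resolution provider.
cohort_bfactor <- function(cohort, particles, provider, min_particles,
                           repeats, seed) {
  members <- particles[particles$particle_id %in% cohort$particle_ids, ]
  sizes <- subset_series(nrow(members), min_particles)
  series <- provider(cohort$label, members, sizes, repeats, seed)
  bfactor_from_fit(rh_fit(series), group = cohort$label)
}

#' Depth-damage profile
#'
#' The full milling-surface damage analysis: interpolate surfaces from
#' annotations, compute per-particle depths, bin into half-open depth
#' groups, draw tomogram-matched controls, estimate each group's and
#' control's B-factor from subset-size resolution series, and summarise
#' the damage as B-factor ratio and extrapolated resolution-difference
#' curves with weighted exponential-decay fits.
#'
#' @param particles a [particle_table()].
#' @param annotations an [annotation_set()] covering the particles'
#'   tomograms.
#' @param resolution_provider see [synthetic_resolution_provider()].
#' @param config a [validate_config()] result (or overrides list).
#' @param out_dir optional directory for CSV/JSON reports.
#' @return list of class `depth_profile` with `particles` (depth columns
#'   added), `groups` (per-bin tibble of B-factors), `points` (damage
#'   curves), `ratio_fit`, `dres_fit`, `thickness`, `config`, `seed`.
#' @export
run_depth_profile <- function(particles, annotations, resolution_provider,
                              config = validate_config(), out_dir = NULL) {
  config <- if (inherits(config, "run_config")) config else
    validate_config(config)
  surfaces <- build_surfaces(annotations, grid_step = config$grid_step)
  particles <- add_depths(particles, surfaces)
  binned <- assign_depth_bins(particles,
                              bin_width = config$depth_bin_width_nm,
                              max_depth = config$depth_max_nm)
  # a Rosenthal-Henderson fit needs >= 2 subset sizes at or above the
  # per-subset floor, so a usable bin holds at least twice the minimum
  usable <- Filter(function(b) length(b) >= 2 * config$min_particles,
                   binned$bins)
  dropped <- setdiff(names(binned$bins), names(usable))
  if (length(dropped)) {
    message(sprintf(
      "bin(s) with too few particles for a subset series skipped: %s",
      paste(dropped, collapse = ", ")))
  }
  if (length(usable) == 0) {
    abort_fib("no depth bin reaches the particle minimum",
              "fib_insufficient_particles")
  }
  seeds <- derive_seeds(config$seed, 2 * length(usable))
  rows <- list(); points <- list()
  for (i in seq_along(usable)) {
    label <- names(usable)[i]
    matched <- draw_matched_control(
      usable[[i]], binned$pool,
      eligibility_floor_nm = config$eligibility_floor_nm,
      seed = seeds[2 * i - 1])
    bg <- cohort_bfactor(matched$group, particles, resolution_provider,
                         config$min_particles, config$repeats, seeds[2 * i])
    bc <- cohort_bfactor(matched$control, particles, resolution_provider,
                         config$min_particles, config$repeats,
                         seeds[2 * i] + 1L)
    rat <- bfactor_ratio(bg$B, bg$sigma_B, bc$B, bc$sigma_B)
    eg <- extrapolate_resolution(bg$fit, config$extrapolate_n)
    ec <- extrapolate_resolution(bc$fit, config$extrapolate_n)
    dres <- resolution_difference(eg$resolution_A, eg$sigma,
                                  ec$resolution_A, ec$sigma)
    mid <- (usable[[i]]$lower + usable[[i]]$upper) / 2
    rows[[label]] <- tibble::tibble(
      group = label, x_mid_nm = mid, n = length(matched$group),
      B = bg$B, sigma_B = bg$sigma_B,
      B_control = bc$B, sigma_B_control = bc$sigma_B)
    points[[label]] <- tibble::tibble(
      group = label, x_mid_nm = mid,
      ratio = rat$ratio, ratio_se = rat$sigma,
      dres_A = dres$delta, dres_se = dres$sigma)
  }
  groups <- dplyr::bind_rows(rows)
  points <- dplyr::bind_rows(points)
  ratio_fit <- fit_exponential_decay(points$x_mid_nm, points$ratio,
                                     points$ratio_se)
  dres_fit <- fit_exponential_decay(points$x_mid_nm, points$dres_A,
                                    points$dres_se)
  thickness <- thickness_summary(particles)
  out <- structure(list(
    particles = particles, groups = groups, points = points,
    ratio_fit = ratio_fit, dres_fit = dres_fit, thickness = thickness,
    config = config, seed = config$seed
  ), class = "depth_profile")
  if (!is.null(out_dir)) write_profile_reports(out, out_dir)
  out
}

#' Backside-damage profile
#'
#' Groups particles by distance to the backside amorphous boundary in
#' half-open 1-um bins, estimates each bin's B-factor, and summarises the
#' extremes and the Spearman trend of B-factor against distance.
#'
#' @param particles a [particle_table()] with a `backside_um` column (or
#'   `acquisition_um` plus lateral coordinates to derive it).
#' @inheritParams run_depth_profile
#' @return list of class `backside_profile` with `groups`, `summary`,
#'   `config`.
#' @export
run_backside_profile <- function(particles, resolution_provider,
                                 config = validate_config(),
                                 out_dir = NULL) {
  config <- if (inherits(config, "run_config")) config else
    validate_config(config)
  particles <- tibble::as_tibble(particles)
  if (!"backside_um" %in% names(particles)) {
    abort_fib("particles lack a backside_um column", "fib_format_error")
  }
  bins <- assign_backside_bins(particles,
                               bin_width = config$backside_bin_width_um,
                               max_um = config$backside_max_um)
  usable <- Filter(function(b) length(b) >= 2 * config$min_particles, bins)
  if (length(usable) == 0) {
    abort_fib("no backside bin reaches the particle minimum",
              "fib_insufficient_particles")
  }
  seeds <- derive_seeds(config$seed, length(usable))
  rows <- list()
  for (i in seq_along(usable)) {
    b <- cohort_bfactor(usable[[i]], particles, resolution_provider,
                        config$min_particles, config$repeats, seeds[i])
    rows[[i]] <- tibble::tibble(
      group = names(usable)[i],
      lower_um = usable[[i]]$lower, upper_um = usable[[i]]$upper,
      n = length(usable[[i]]), B = b$B, sigma_B = b$sigma_B)
  }
  groups <- dplyr::bind_rows(rows)
  out <- structure(list(
    groups = groups,
    summary = backside_group_summary(groups$B),
    config = config, seed = config$seed
  ), class = "backside_profile")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(groups),
              file.path(out_dir, "backside_groups.csv"), row.names = FALSE)
    jsonlite::write_json(out$summary,
                         file.path(out_dir, "backside_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# CSV/JSON report bundle for a depth profile.
write_profile_reports <- function(profile, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(profile$groups),
            file.path(out_dir, "depth_groups.csv"), row.names = FALSE)
  long <- rbind(
    data.frame(bin = profile$points$group,
               x_mid_nm = profile$points$x_mid_nm,
               value = profile$points$ratio,
               se = profile$points$ratio_se, kind = "ratio"),
    data.frame(bin = profile$points$group,
               x_mid_nm = profile$points$x_mid_nm,
               value = profile$points$dres_A,
               se = profile$points$dres_se, kind = "dres")
  )
  write.csv(long, file.path(out_dir, "damage_curves.csv"),
            row.names = FALSE)
  fits <- list(ratio = unclass(profile$ratio_fit),
               dres = unclass(profile$dres_fit),
               seed = profile$seed)
  jsonlite::write_json(fits, file.path(out_dir, "decay_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile: %d bins, dres decay k = %.3f nm^-1 (R^2 %.2f)>\n",
              nrow(x$groups), x$dres_fit$k, x$dres_fit$r_squared))
  invisible(x)
}

#' @export
print.backside_profile <- function(x, ...) {
  cat(sprintf(
    "<backside_profile: %d bins, B in [%.0f, %.0f] A^2, Spearman r = %.2f>\n",
    nrow(x$groups), x$summary$min_B, x$summary$max_B, x$summary$spearman_r))
  invisible(x)
}
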