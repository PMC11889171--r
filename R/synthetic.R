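#' Synthetic study configuration
#'
#' Parameters of the synthetic lamella generator. The defaults emulate the
#' regime of a 60 nA xenon PFIB bulk-milling session on high-pressure
#' frozen *E. coli*: ~190 +- 30 nm thick slab lamellae imaged at binning 8
#' (15.2 A/voxel), a bulk ribosome B-factor near 300 A^2 inflated to
#' ~1400 A^2 at the milling surfaces, and a damage decay length of 5.4 nm
#' (rate 0.185 nm^-1).
#'
#' The damage model is multiplicative exponential B-factor inflation,
#' `B(d) = B_bulk (1 + (delta_B/B_bulk) exp(-d/lambda))`; it is the
#' generator's declared ground truth for recovery tests, not a mechanistic
#' claim.
#'
#' @param n_tomograms number of tomograms.
#' @param nx,ny,nz tomogram dimensions in voxels.
#' @param pixel_size_A voxel size, angstrom (binning-8 default 15.2).
#' @param thickness_mean_nm,thickness_sd_nm slab thickness distribution.
#' @param tilt_max_deg maximum slab tilt about the slice axis, degrees.
#' @param roughness_amp_voxels,roughness_period_voxels sinusoidal surface
#'   roughness amplitude and period.
#' @param n_particles_per_tomogram particles placed per tomogram.
#' @param exclusion_margin_nm particle-free margin below each surface.
#' @param annotation_interval slice spacing of emitted annotations.
#' @param annotation_spacing point spacing along each annotated polyline.
#' @param grid_step lateral grid step of the true surface sheets, voxels.
#' @param B_bulk_A2,delta_B_A2,lambda_nm damage model parameters.
#' @param c0 intercept of the generative Rosenthal-Henderson line, 1/A^2.
#' @param sigma_y resolution noise SD on the `1/resolution^2` scale.
#' @param min_particles,repeats subset-series floor and repeat count.
#' @param backside_min_um,backside_max_um range of per-tomogram acquisition
#'   distances to the backside amorphous boundary.
#' @param seed master RNG seed recorded in every emitted artifact.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tomograms = 20,
                             nx = 512, ny = 512, nz = 256,
                             pixel_size_A = 15.2,
                             thickness_mean_nm = 190,
                             thickness_sd_nm = 30,
                             tilt_max_deg = 5,
                             roughness_amp_voxels = 2,
                             roughness_period_voxels = 400,
                             n_particles_per_tomogram = 4000,
                             exclusion_margin_nm = 0,
                             annotation_interval = 100,
                             annotation_spacing = 32,
                             grid_step = 10,
                             B_bulk_A2 = 300,
                             delta_B_A2 = 1100,
                             lambda_nm = 5.4,
                             c0 = 0.004,
                             sigma_y = 2.5e-4,
                             min_particles = 400,
                             repeats = 3,
                             backside_min_um = 0.2,
                             backside_max_um = 4.8,
                             seed = 1) {
  cfg <- as.list(environment())
  positive <- c("nx", "ny", "nz", "pixel_size_A", "thickness_mean_nm",
                "n_particles_per_tomogram", "annotation_interval",
                "grid_step", "B_bulk_A2", "lambda_nm", "min_particles",
                "repeats")
  for (p in positive) {
    if (!is_scalar_number(cfg[[p]]) || cfg[[p]] <= 0) {
      abort_fib(sprintf("config field '%s' must be positive", p),
                "fib_config_error")
    }
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Depth-dependent ground-truth B-factor
#'
#' `B(d) = B_bulk (1 + (delta_B/B_bulk) exp(-d/lambda))`: bulk value far
#' from the milling surfaces, inflated near them.
#'
#' @param depth_nm distance(s) from the nearer milling surface, nm.
#' @param config a [synthetic_config()].
#' @return B-factor(s), A^2.
#' @export
damage_bfactor <- function(depth_nm, config) {
  config$B_bulk_A2 *
    (1 + (config$delta_B_A2 / config$B_bulk_A2) *
       exp(-depth_nm / config$lambda_nm))
}

# Analytic height of one surface of one synthetic tomogram at (u, s).
# geom holds the drawn per-tomogram parameters.
true_height <- function(geom, sheet, u, s, config) {
  half <- geom$thickness_vox / 2
  base <- geom$z_centre + if (sheet == "front") -half else half
  tilt <- tan(geom$tilt_deg * pi / 180) * (s - geom$s_centre)
  ph <- if (sheet == "front") geom$phase_front else geom$phase_back
  rough <- config$roughness_amp_voxels *
    (sin(2 * pi * u / config$roughness_period_voxels + ph[1]) +
       sin(2 * pi * s / config$roughness_period_voxels + ph[2]))
  base + tilt + rough
}

#' Simulate lamella geometry
#'
#' Draws per-tomogram slab thickness, tilt and surface roughness, builds
#' the true boundary sheets on a fine lateral grid, and emits sparse
#' annotations by sampling the true surfaces every `annotation_interval`
#' slices (emulating manual annotation).
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed; defaults to the config's.
#' @return list with `tomograms` (per tomogram: `front`/`back` true
#'   [interpolate_surface()]-style sheets, drawn parameters) and
#'   `annotations` (an [annotation_set()] across tomograms).
#' @export
simulate_geometry <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- derive_seeds(seed, config$n_tomograms)
  vox_per_nm <- 10 / config$pixel_size_A
  tomograms <- list()
  ann_rows <- list()
  for (t in seq_len(config$n_tomograms)) {
    tomo_id <- sprintf("TS_%03d", t)
    geom <- with_seed(seeds[t], {
      thick <- NA_real_
      for (try in 1:100) {
        thick <- rnorm(1, config$thickness_mean_nm, config$thickness_sd_nm)
        if (thick > 0) break
        warning("non-positive thickness drawn; redrawing")
        thick <- NA_real_
      }
      if (is.na(thick)) {
        abort_fib("could not draw a positive thickness in 100 attempts",
                  "fib_config_error")
      }
      list(
        thickness_nm = thick,
        thickness_vox = thick * vox_per_nm,
        tilt_deg = runif(1, -config$tilt_max_deg, config$tilt_max_deg),
        z_centre = config$nz / 2,
        s_centre = (config$ny - 1) / 2,
        phase_front = runif(2, 0, 2 * pi),
        phase_back = runif(2, 0, 2 * pi),
        acquisition_um = runif(1, config$backside_min_um,
                               config$backside_max_um)
      )
    })
    u_grid <- unique(c(seq(0, config$nx - 1, by = config$grid_step),
                       config$nx - 1))
    s_grid <- unique(c(seq(0, config$ny - 1, by = config$grid_step),
                       config$ny - 1))
    sheets <- lapply(c(front = "front", back = "back"), function(sh) {
      h <- outer(u_grid, s_grid,
                 function(u, s) true_height(geom, sh, u, s, config))
      structure(list(u = u_grid, s = s_grid, h = h,
                     grid_step = config$grid_step, role = sh),
                class = "surface_sheet")
    })
    ann_slices <- unique(c(seq(0, config$ny - 1,
                               by = config$annotation_interval),
                           config$ny - 1))
    ann_u <- unique(c(seq(0, config$nx - 1, by = config$annotation_spacing),
                      config$nx - 1))
    for (sh in c("front", "back")) {
      for (sl in ann_slices) {
        ann_rows[[length(ann_rows) + 1L]] <- tibble::tibble(
          tomogram_id = tomo_id, sheet = sh, slice_index = sl,
          point_u = ann_u,
          point_v = true_height(geom, sh, ann_u, sl, config))
      }
    }
    tomograms[[tomo_id]] <- c(geom, sheets)
  }
  list(tomograms = tomograms,
       annotations = annotation_set(dplyr::bind_rows(ann_rows)),
       seed = seed)
}

#' Simulate particles within the slab
#'
#' Places particles uniformly between the two true surfaces (optionally
#' inset by an exclusion margin), stores the ground-truth depth alongside
#' so the geometry module can be validated against it, and assigns
#' backside distances from the per-tomogram acquisition distance plus the
#' particle's lateral offset from the tomogram centre.
#'
#' The stored `true_depth_nm` is the perpendicular distance to the nearer
#' surface plane (vertical gap times the cosine of the slab tilt); for
#' rough surfaces it is exact up to the roughness-slope correction.
#'
#' @param config a [synthetic_config()].
#' @param geometry result of [simulate_geometry()].
#' @param seed RNG seed.
#' @return a [particle_table()] with `true_depth_nm`, `backside_um`,
#'   `acquisition_um` columns.
#' @export
simulate_particles <- function(config, geometry, seed = config$seed + 1) {
  stopifnot(inherits(config, "synthetic_config"))
  n_per <- config$n_particles_per_tomogram
  if (n_per <= 0) abort_fib("zero particle density", "fib_config_error")
  vox_per_nm <- 10 / config$pixel_size_A
  margin_vox <- config$exclusion_margin_nm * vox_per_nm
  seeds <- derive_seeds(seed, length(geometry$tomograms))
  rows <- list()
  for (t in seq_along(geometry$tomograms)) {
    tomo_id <- names(geometry$tomograms)[t]
    geom <- geometry$tomograms[[tomo_id]]
    rows[[t]] <- with_seed(seeds[t], {
      u <- runif(n_per, 0, config$nx - 1)
      s <- runif(n_per, 0, config$ny - 1)
      hf <- true_height(geom, "front", u, s, config)
      hb <- true_height(geom, "back", u, s, config)
      lo <- hf + margin_vox
      hi <- hb - margin_vox
      if (any(hi <= lo)) {
        abort_fib("exclusion margin leaves no interior: zero particles",
                  "fib_config_error")
      }
      z <- runif(n_per, lo, hi)
      cos_tilt <- cos(geom$tilt_deg * pi / 180)
      true_depth_vox <- pmin(z - hf, hb - z) * cos_tilt
      offset_um <- (u - (config$nx - 1) / 2) * config$pixel_size_A * 1e-4
      tibble::tibble(
        particle_id = sprintf("%s_P%05d", tomo_id, seq_len(n_per)),
        tomogram_id = tomo_id,
        x = u, y = s, z = z,
        pixel_size_A = config$pixel_size_A,
        true_depth_nm = true_depth_vox / vox_per_nm,
        acquisition_um = geom$acquisition_um,
        backside_um = suppressMessages(
          backside_particle_distance(geom$acquisition_um, offset_um))
      )
    })
  }
  particle_table(dplyr::bind_rows(rows))
}

#' Simulate a subset-size resolution series
#'
#' Generative Rosenthal-Henderson model for a particle set at depth `d`:
#' `y = (2/B(d)) ln N + c0 + eps` with `eps ~ N(0, sigma_y)`, resolution
#' `1/sqrt(y)`, three independent repeats by default. Draws giving
#' non-positive `y` are redrawn (hard error after 100 attempts).
#'
#' @param depth_nm representative depth of the set (nm).
#' @param sizes subset sizes (from [subset_series()]).
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @param group label for the emitted series.
#' @return a [resolution_series()].
#' @export
simulate_resolution_series <- function(depth_nm, sizes, config,
                                       seed = config$seed,
                                       group = "group") {
  B <- damage_bfactor(depth_nm, config)
  if (B <= 0) abort_fib("non-positive ground-truth B-factor",
                        "fib_config_error")
  mu <- (2 / B) * log(sizes) + config$c0
  vals <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = length(sizes), ncol = config$repeats)
    for (r in seq_len(config$repeats)) {
      for (i in seq_along(sizes)) {
        y <- NA_real_
        for (try in 1:100) {
          y <- mu[i] + rnorm(1, 0, config$sigma_y)
          if (y > 0) break
          y <- NA_real_
        }
        if (is.na(y)) {
          abort_fib("could not draw positive 1/res^2 in 100 attempts",
                    "fib_config_error")
        }
        out[i, r] <- y
      }
    }
    out
  })
  resolution_series(
    group = group,
    repeats = rep(seq_len(config$repeats), each = length(sizes)),
    n_particles = rep(sizes, times = config$repeats),
    resolution_A = 1 / sqrt(as.numeric(vals)),
    min_particles = config$min_particles
  )
}

#' Simulate an FSC-controlled half-map pair
#'
#' Builds two volumes sharing a white Gaussian signal plus independent
#' per-half noise whose per-shell variance follows a designed SSNR
#' profile, so the expected FSC `SSNR/(SSNR+1)` crosses 0.143 at the
#' target spatial frequency. With `target_crossover_freq = NULL` no noise
#' is added and the FSC is ~1 in every shell.
#'
#' @param target_crossover_freq designed 0.143 crossover, 1/A; must be
#'   below Nyquist.
#' @param size cube edge length in voxels.
#' @param voxel_size_A voxel size, angstrom.
#' @param seed RNG seed.
#' @return list with `half_a`, `half_b` ([volume_grid()]s).
#' @export
simulate_half_maps <- function(target_crossover_freq = NULL, size = 64,
                               voxel_size_A = 1.9, seed = 1) {
  nyq_freq <- 1 / nyquist_resolution(voxel_size_A)
  if (!is.null(target_crossover_freq) &&
      target_crossover_freq >= nyq_freq) {
    abort_fib("designed crossover is at or beyond Nyquist",
              "fib_config_error")
  }
  dims <- c(size, size, size)
  vols <- with_seed(seed, list(
    signal = array(rnorm(prod(dims)), dims),
    n1 = array(rnorm(prod(dims)), dims),
    n2 = array(rnorm(prod(dims)), dims)
  ))
  if (is.null(target_crossover_freq)) {
    return(list(half_a = volume_grid(vols$signal, voxel_size_A),
                half_b = volume_grid(vols$signal, voxel_size_A)))
  }
  shell <- fourier_shell_index(dims)
  freq <- shell / (size * voxel_size_A)
  thr <- 0.143
  ssnr <- (thr / (1 - thr)) *
    exp(12 * (target_crossover_freq - freq) / target_crossover_freq)
  noise_scale <- array(1 / sqrt(ssnr), dims)
  shape_noise <- function(n) {
    Re(fft(fft(n) * noise_scale, inverse = TRUE)) / prod(dims)
  }
  list(
    half_a = volume_grid(vols$signal + shape_noise(vols$n1), voxel_size_A),
    half_b = volume_grid(vols$signal + shape_noise(vols$n2), voxel_size_A)
  )
}

#' Write a self-contained synthetic input bundle
#'
#' Generates geometry and particles and writes everything the pipeline
#' consumes: `particles.star`, `annotations.csv`, `config.yaml` and
#' `ground_truth.json` (true damage parameters, per-tomogram thicknesses,
#' seed). On a partial write the directory is cleaned up before the error
#' propagates.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created).
#' @param seed master seed; defaults to the config's.
#' @return `dir`, invisibly.
#' @export
build_fixture_bundle <- function(config, dir, seed = config$seed) {
  created <- !dir.exists(dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tryCatch({
    geometry <- simulate_geometry(config, seed = seed)
    particles <- simulate_particles(config, geometry, seed = seed + 1)
    write_particle_star(particles, file.path(dir, "particles.star"))
    write_annotations(geometry$annotations,
                      file.path(dir, "annotations.csv"))
    cfg <- unclass(config)
    cfg$seed <- seed
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
    truth <- list(
      lambda_nm = config$lambda_nm,
      decay_rate_per_nm = 1 / config$lambda_nm,
      B_bulk_A2 = config$B_bulk_A2,
      delta_B_A2 = config$delta_B_A2,
      c0 = config$c0,
      seed = seed,
      thickness_nm = vapply(geometry$tomograms, `[[`, numeric(1),
                            "thickness_nm"),
      acquisition_um = vapply(geometry$tomograms, `[[`, numeric(1),
                              "acquisition_um")
    )
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
  }, error = function(e) {
    if (created) unlink(dir, recursive = TRUE)
    stop(e)
  })
}
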