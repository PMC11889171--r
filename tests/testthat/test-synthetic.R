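test_that("zero roughness and tilt give parallel planes at the drawn thickness", {
  cfg <- tiny_synthetic_config(tilt_max_deg = 0, roughness_amp_voxels = 0,
                               seed = 3)
  geo <- simulate_geometry(cfg)
  for (tomo in geo$tomograms) {
    expect_true(all(abs(tomo$front$h - tomo$front$h[1, 1]) < 1e-12))
    sep_nm <- (tomo$back$h[1, 1] - tomo$front$h[1, 1]) *
      cfg$pixel_size_A / 10
    expect_equal(sep_nm, tomo$thickness_nm, tolerance = 1e-9)
  }
})

test_that("interpolating emitted annotations reproduces the true sheets", {
  cfg <- tiny_synthetic_config(seed = 12)
  geo <- simulate_geometry(cfg)
  sheets <- build_surfaces(geo$annotations, grid_step = cfg$grid_step)
  for (tm in names(geo$tomograms)) {
    true_h <- geo$tomograms[[tm]]$front$h
    u <- geo$tomograms[[tm]]$front$u
    s <- geo$tomograms[[tm]]$front$s
    got <- outer(u, s, function(uu, ss) sheet_height(sheets[[tm]]$front,
                                                     uu, ss))
    # bounded by the roughness amplitude (interpolation between
    # annotated slices cannot do better than the surface variation)
    bound <- 2 * cfg$roughness_amp_voxels + 1e-6
    expect_lt(max(abs(got - true_h), na.rm = TRUE), bound)
  }
})

test_that("planar-slab particle depths equal the stored ground truth", {
  cfg <- tiny_synthetic_config(tilt_max_deg = 0, roughness_amp_voxels = 0,
                               n_particles_per_tomogram = 200, seed = 4)
  geo <- simulate_geometry(cfg)
  parts <- simulate_particles(cfg, geo)
  tm <- names(geo$tomograms)[1]
  sub <- parts[parts$tomogram_id == tm, ]
  d <- particle_depth(sub, geo$tomograms[[tm]]$front,
                      geo$tomograms[[tm]]$back)
  expect_equal(d$depth_nm, sub$true_depth_nm, tolerance = 1e-9)
  expect_true(all(d$inside))
})

test_that("relative depth is uniform across seeds", {
  cfg <- synthetic_config(n_tomograms = 1, nx = 96, ny = 96, nz = 128,
                          tilt_max_deg = 0, roughness_amp_voxels = 0,
                          n_particles_per_tomogram = 300,
                          annotation_interval = 40)
  rejections <- 0L
  for (seed in 1:100) {
    geo <- simulate_geometry(cfg, seed = seed)
    parts <- simulate_particles(cfg, geo, seed = seed + 1000)
    rel <- parts$true_depth_nm / geo$tomograms[[1]]$thickness_nm
    p <- suppressWarnings(
      stats::ks.test(rel, stats::punif, 0, 0.5)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 5L)
})

test_that("exclusion margin of half the slab leaves no room for particles", {
  cfg <- tiny_synthetic_config(tilt_max_deg = 0, roughness_amp_voxels = 0,
                               thickness_sd_nm = 0,
                               exclusion_margin_nm = 95, seed = 6)
  geo <- simulate_geometry(cfg)
  expect_error(simulate_particles(cfg, geo), class = "fib_config_error")
})

test_that("damage model closed form and asymptote", {
  cfg <- synthetic_config(B_bulk_A2 = 300, delta_B_A2 = 1100,
                          lambda_nm = 5.4, n_tomograms = 1,
                          n_particles_per_tomogram = 10)
  expect_equal(damage_bfactor(7.5, cfg),
               300 * (1 + (1100 / 300) * exp(-7.5 / 5.4)),
               tolerance = 1e-12)
  expect_equal(damage_bfactor(7.5, cfg), 574, tolerance = 1)
  expect_equal(damage_bfactor(1e6, cfg), 300, tolerance = 1e-9)
})

test_that("simulated series recover B(d) within the fit CI on average", {
  cfg <- tiny_synthetic_config(seed = 1)
  d <- 12.5
  slopes <- vapply(1:100, function(seed) {
    s <- simulate_resolution_series(d, c(4000, 2000, 1000, 500), cfg,
                                    seed = seed)
    rh_fit(s)$slope
  }, numeric(1))
  true_slope <- 2 / damage_bfactor(d, cfg)
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - true_slope), 3 * mc_se)
})

test_that("fixture bundles are deterministic in the seed and carry truth", {
  cfg <- tiny_synthetic_config(n_particles_per_tomogram = 50,
                               thickness_mean_nm = 150, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  build_fixture_bundle(cfg, d1, seed = 9)
  build_fixture_bundle(cfg, d2, seed = 9)
  build_fixture_bundle(cfg, d3, seed = 10)
  s1 <- readLines(file.path(d1, "particles.star"))
  expect_identical(s1, readLines(file.path(d2, "particles.star")))
  expect_false(identical(s1, readLines(file.path(d3, "particles.star"))))
  truth <- jsonlite::read_json(file.path(d1, "ground_truth.json"))
  expect_equal(truth$lambda_nm, cfg$lambda_nm)
  expect_equal(truth$seed, 9)
  parts <- read_particle_star(file.path(d1, "particles.star"))
  ann <- read_annotations(file.path(d1, "annotations.csv"))
  expect_s3_class(parts, "particle_table")
  expect_s3_class(ann, "annotation_set")
  expect_true("true_depth_nm" %in% names(parts))
})
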