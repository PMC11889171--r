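test_that("a single annotated slice extrudes to a constant sheet", {
  ann <- data.frame(slice_index = 0, point_u = c(0, 50, 100),
                    point_v = 100)
  sheet <- interpolate_surface(ann, grid_step = 10)
  expect_true(all(sheet$h == 100))
  expect_equal(range(sheet$u), c(0, 100))
})

test_that("heights blend linearly between annotated slices and clamp beyond", {
  ann <- data.frame(slice_index = rep(c(0, 100), each = 2),
                    point_u = c(0, 100, 0, 100),
                    point_v = c(100, 100, 200, 200))
  sheet <- interpolate_surface(ann, grid_step = 10)
  expect_equal(sheet_height(sheet, 50, 50), 150)
  expect_equal(sheet_height(sheet, 50, 0), 100)
  expect_equal(sheet_height(sheet, 50, 100), 200)
})

test_that("interpolation reproduces annotated points exactly", {
  set.seed(11)
  slices <- c(0, 100, 200)
  u_pts <- seq(0, 120, by = 30)
  ann <- do.call(rbind, lapply(slices, function(sl) {
    data.frame(slice_index = sl, point_u = u_pts,
               point_v = 100 + 5 * sin(u_pts / 20) + sl / 10)
  }))
  sheet <- interpolate_surface(ann, grid_step = 5)
  for (sl in slices) {
    got <- sheet_height(sheet, u_pts, rep(sl, length(u_pts)))
    want <- ann$point_v[ann$slice_index == sl]
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("degenerate annotations are rejected", {
  expect_error(interpolate_surface(data.frame(slice_index = numeric(),
                                              point_u = numeric(),
                                              point_v = numeric())),
               class = "fib_empty_input")
  expect_error(interpolate_surface(data.frame(slice_index = 0, point_u = 5,
                                              point_v = 10)),
               "2 points", class = "fib_format_error")
})

test_that("planar slab depths, thickness and sign convention are exact", {
  # front at z = 0 nm, back at z = 200 nm (pixel 10 A so voxel == nm)
  front <- make_plane(0); back <- make_plane(200)
  parts <- particle_table(tibble::tibble(
    particle_id = c("in", "deep", "below"), tomogram_id = "T",
    x = 100, y = 100, z = c(50, 120, -10), pixel_size_A = 10))
  d <- particle_depth(parts, front, back)
  expect_equal(d$depth_nm, c(50, 80, 10), tolerance = 1e-9)
  expect_equal(d$thickness_nm, rep(200, 3), tolerance = 1e-9)
  expect_identical(d$inside, c(TRUE, TRUE, FALSE))
  # complementarity: depth to the two sheets sums to the thickness
  d_front <- cpp_dist_for_test(parts, front)
  d_back <- cpp_dist_for_test(parts, back)
  expect_equal(d_front[1] + d_back[1], 200, tolerance = 1e-9)
})

test_that("depths match a brute-force dense-sampling oracle on a tilted rough sheet", {
  set.seed(42)
  extent <- 100; step <- 2
  g <- seq(0, extent, by = step)
  hfun <- function(u, s) 50 + tan(10 * pi / 180) * u + 1.5 * sin(s / 12)
  sheet <- structure(list(u = g, s = g, h = outer(g, g, hfun),
                          grid_step = step, role = "front"),
                     class = "surface_sheet")
  n <- 200
  parts <- particle_table(tibble::tibble(
    particle_id = sprintf("P%03d", 1:n), tomogram_id = "T",
    x = runif(n, 5, 95), y = runif(n, 5, 95), z = runif(n, 40, 90),
    pixel_size_A = 10))
  got <- cpp_dist_for_test(parts, sheet)
  # oracle: exhaustive nearest point over 10^6 densely sampled surface points
  gd <- seq(0, extent, length.out = 1000)
  dense <- expand.grid(u = gd, s = gd)
  dense$h <- hfun(dense$u, dense$s)
  oracle <- vapply(seq_len(n), function(i) {
    sqrt(min((dense$u - parts$x[i])^2 + (dense$s - parts$y[i])^2 +
               (dense$h - parts$z[i])^2))
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), step)  # within one grid step
})

test_that("local thickness reads the vertical sheet separation and flags crossings", {
  front <- make_plane(0)
  g <- front$u
  back <- structure(list(u = g, s = g,
                         h = outer(g, g, function(u, s) 200 + 0.1 * u),
                         grid_step = 10, role = "back"),
                    class = "surface_sheet")
  t1 <- local_thickness(front, back, cbind(100, 50), pixel_size_A = 10)
  expect_equal(t1$thickness_nm, 210)
  expect_false(t1$crossed)
  t2 <- local_thickness(back, front, cbind(100, 50), pixel_size_A = 10)
  expect_true(t2$crossed)
  expect_true(is.na(t2$thickness_nm))
})

test_that("thickness summary aggregates per-tomogram means", {
  rec <- tibble::tibble(tomogram_id = rep(c("a", "b", "c"), each = 2),
                        thickness_nm = c(100, 100, 200, 200, 300, 300))
  s <- thickness_summary(rec)
  expect_equal(s$mean_nm, 200)
  expect_equal(s$median_nm, 200)
  expect_equal(s$sd_nm, 100)
  one <- tibble::tibble(tomogram_id = "a", thickness_nm = 150)
  expect_warning(s1 <- thickness_summary(one), "single")
  expect_equal(s1$sd_nm, 0)
  expect_true(s1$single_tomogram)
  expect_error(thickness_summary(tibble::tibble(tomogram_id = "a",
                                                thickness_nm = NA_real_)),
               class = "fib_empty_input")
})

test_that("simulated thickness distribution is recovered by the summary", {
  cfg <- synthetic_config(n_tomograms = 50, nx = 64, ny = 64,
                          n_particles_per_tomogram = 10,
                          annotation_interval = 30,
                          thickness_mean_nm = 200, thickness_sd_nm = 30,
                          seed = 5)
  geo <- simulate_geometry(cfg)
  thick <- vapply(geo$tomograms, `[[`, numeric(1), "thickness_nm")
  se <- 30 / sqrt(50)
  expect_lt(abs(mean(thick) - 200), 3 * se)
})
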