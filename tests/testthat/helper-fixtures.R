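# Fixtures built in code: tiny particle tables, planar slabs, STAR text.

make_particles <- function(n = 3, tomogram_id = "TS_001",
                           pixel_size_A = 15.2, ...) {
  particle_table(tibble::tibble(
    particle_id = sprintf("%s_P%03d", tomogram_id, seq_len(n)),
    tomogram_id = tomogram_id,
    x = seq(10, 10 + 5 * (n - 1), by = 5),
    y = seq(20, 20 + 5 * (n - 1), by = 5),
    z = seq(30, 30 + 2 * (n - 1), by = 2),
    pixel_size_A = pixel_size_A,
    ...
  ))
}

# Planar sheet at constant height (voxel units) over [0, extent]^2.
make_plane <- function(height, extent = 200, step = 10, role = "front") {
  g <- seq(0, extent, by = step)
  structure(list(u = g, s = g,
                 h = matrix(height, length(g), length(g)),
                 grid_step = step, role = role),
            class = "surface_sheet")
}

# Annotations for a planar slab: front at z = z0, back at z = z0 + t.
make_slab_annotations <- function(tomogram_id = "TS_001", z_front = 50,
                                  z_back = 150, extent = 200, n_slices = 3) {
  slices <- round(seq(0, extent, length.out = n_slices))
  u_pts <- seq(0, extent, by = 40)
  rows <- expand.grid(sheet = c("front", "back"), slice_index = slices,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    data.frame(tomogram_id = tomogram_id, sheet = rows$sheet[i],
               slice_index = rows$slice_index[i], point_u = u_pts,
               point_v = if (rows$sheet[i] == "front") z_front else z_back)
  }))
  annotation_set(out)
}

# Particle table spread over tomograms with explicit depths, for cohort tests.
make_depth_particles <- function(depths, tomogram_ids) {
  particle_table(tibble::tibble(
    particle_id = sprintf("P%05d", seq_along(depths)),
    tomogram_id = tomogram_ids,
    x = 0, y = 0, z = 0,
    pixel_size_A = 15.2,
    depth_nm = depths
  ))
}

# A noiseless resolution series on the line y = m ln(N) + c.
make_series_on_line <- function(m, c, sizes = c(8000, 4000, 2000, 1000),
                                repeats = 2, group = "g") {
  y <- m * log(sizes) + c
  resolution_series(group,
                    repeats = rep(seq_len(repeats), each = length(sizes)),
                    n_particles = rep(sizes, repeats),
                    resolution_A = rep(1 / sqrt(y), repeats))
}

tiny_synthetic_config <- function(...) {
  defaults <- list(n_tomograms = 2, nx = 128, ny = 128, nz = 128,
                   n_particles_per_tomogram = 300,
                   annotation_interval = 40, annotation_spacing = 16)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# Distance of particles to a single sheet in nm, via the compiled kernel.
cpp_dist_for_test <- function(parts, sheet) {
  fibdamage:::cpp_grid_surface_dist(cbind(parts$x, parts$y, parts$z),
                                    sheet$u, sheet$s, sheet$h) *
    parts$pixel_size_A[1] / 10
}
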