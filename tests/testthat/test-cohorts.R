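test_that("depth bins are half-open and partition the input", {
  parts <- make_depth_particles(c(7.3, 5, 59.999, 60, 0, 4.999, 75, NA),
                                rep("T1", 8))
  res <- assign_depth_bins(parts)
  expect_equal(res$bins$depth_05_10$particle_ids,
               parts$particle_id[c(1, 2)])  # 7.3 and the 5.0 edge
  expect_equal(res$bins$depth_55_60$particle_ids, parts$particle_id[3])
  expect_equal(res$bins$depth_00_05$particle_ids,
               parts$particle_id[c(5, 6)])
  # depth 60 is excluded (half-open) and lands in the control pool
  expect_true(parts$particle_id[4] %in% res$pool$particle_id)
  expect_true(parts$particle_id[7] %in% res$pool$particle_id)
  binned_ids <- unname(unlist(lapply(res$bins, `[[`, "particle_ids")))
  expect_equal(sort(c(binned_ids, res$pool$particle_id)),
               sort(parts$particle_id[-8]))
  expect_false(anyDuplicated(binned_ids) > 0)
})

test_that("uniform-slab bin counts match the binomial expectation", {
  # uniform depths in [0, 100] (= half of a 200 nm slab, both surfaces fold)
  n <- 10000
  depths <- withr::with_seed(21, runif(n, 0, 100))
  parts <- make_depth_particles(depths, rep("T1", n))
  res <- assign_depth_bins(parts)
  p <- 5 / 100
  expected <- n * p
  sd_bin <- sqrt(n * p * (1 - p))
  counts <- vapply(res$bins, length, integer(1))
  expect_length(counts, 12)
  expect_true(all(abs(counts - expected) < 4 * sd_bin))
})

test_that("backside distances offset by the lateral displacement", {
  expect_equal(backside_particle_distance(2.0, 0.5), 2.5)
  expect_equal(backside_particle_distance(1.0, 0), 1.0)
  expect_message(d <- backside_particle_distance(1.0, -1.2), "flagged")
  expect_true(is.na(d))
  expect_error(backside_particle_distance(-0.5, 0),
               class = "fib_format_error")
})

test_that("matched controls equalize per-tomogram counts against the pool", {
  group <- fibdamage:::new_cohort(
    "depth_05_10",
    ids = sprintf("g%02d", 1:5),
    tomogram_ids = c("T1", "T1", "T1", "T2", "T2"),
    lower = 5, upper = 10, unit = "nm")
  pool <- tibble::tibble(
    particle_id = sprintf("p%02d", 1:6),
    tomogram_id = c(rep("T1", 5), "T2"),
    depth_nm = c(80, 90, 100, 70, 65, 75))
  res <- draw_matched_control(group, pool, eligibility_floor_nm = 60,
                              seed = 3)
  expect_equal(as.integer(res$control$counts_by_tomogram[c("T1", "T2")]),
               c(3L, 1L))
  expect_equal(as.integer(res$group$counts_by_tomogram[c("T1", "T2")]),
               c(3L, 1L))
  expect_equal(length(res$control), length(res$group))
})

test_that("control draws are reproducible and respect the floor", {
  set.seed(99)
  n <- 400
  parts <- make_depth_particles(runif(n, 0, 95),
                                sample(paste0("T", 1:4), n, replace = TRUE))
  res <- assign_depth_bins(parts)
  group <- res$bins$depth_05_10
  for (seed in 1:20) {
    mc <- draw_matched_control(group, res$pool, eligibility_floor_nm = 60,
                               seed = seed)
    pool_depth <- setNames(res$pool$depth_nm, res$pool$particle_id)
    expect_true(all(pool_depth[mc$control$particle_ids] > 60))
    got <- as.integer(mc$control$counts_by_tomogram)
    want <- as.integer(mc$group$counts_by_tomogram[
      names(mc$control$counts_by_tomogram)])
    expect_equal(got, want)
  }
  a <- draw_matched_control(group, res$pool, 60, seed = 7)
  b <- draw_matched_control(group, res$pool, 60, seed = 7)
  expect_identical(sort(a$control$particle_ids),
                   sort(b$control$particle_ids))
  c2 <- draw_matched_control(group, res$pool, 60, seed = 8)
  expect_false(identical(sort(a$control$particle_ids),
                         sort(c2$control$particle_ids)))
})

test_that("threshold sets draw exactly n per stratum, reproducibly", {
  set.seed(5)
  n_tot <- 2000
  parts <- make_depth_particles(runif(n_tot, 0, 95),
                                sample(paste0("T", 1:5), n_tot, TRUE))
  sets <- split_threshold_sets(parts, threshold = 30, n = 500, seed = 2)
  expect_named(sets, c("all", "lt_threshold", "gt_threshold"))
  expect_true(all(vapply(sets, length, integer(1)) == 500))
  depths <- setNames(parts$depth_nm, parts$particle_id)
  expect_true(all(depths[sets$lt_threshold$particle_ids] < 30))
  expect_true(all(depths[sets$gt_threshold$particle_ids] >= 30))
  again <- split_threshold_sets(parts, threshold = 30, n = 500, seed = 2)
  expect_identical(sets$all$particle_ids, again$all$particle_ids)
  other <- split_threshold_sets(parts, threshold = 30, n = 500, seed = 3)
  expect_false(identical(sort(sets$all$particle_ids),
                         sort(other$all$particle_ids)))
  expect_error(split_threshold_sets(parts, n = 1200),
               "has only", class = "fib_insufficient_particles")
})
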