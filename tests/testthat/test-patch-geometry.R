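test_that("axis positions anchor endpoints and round halves down", {
  expect_equal(plan_axis_positions(91, 48, 2), c(0L, 43L))
  expect_equal(plan_axis_positions(115, 48, 3), c(0L, 33L, 67L))
  expect_equal(plan_axis_positions(91, 91, 1), 0L)
  expect_error(plan_axis_positions(91, 48, 1), "cannot cover")
  expect_error(plan_axis_positions(100, 10, 3), "cannot cover")
  expect_error(plan_axis_positions(91, 120, 2), "exceeds")
  # without the coverage demand a single small patch is fine
  expect_equal(plan_axis_positions(91, 48, 1, require_coverage = FALSE), 0L)
})

test_that("published grid plans have the right patch counts and cover", {
  vols <- c(91, 115, 91)
  cases <- list(
    list(patch = c(48, 48, 48), counts = c(2, 3, 2), n = 12),
    list(patch = c(64, 64, 64), counts = c(2, 2, 2), n = 8),
    list(patch = c(91, 25, 91), counts = c(1, 6, 1), n = 6),
    list(patch = c(32, 32, 32), counts = c(3, 4, 3), n = 36),
    list(patch = c(24, 24, 24), counts = c(4, 5, 4), n = 80)
  )
  for (cs in cases) {
    plan <- plan_grid(vols, cs$patch, cs$counts)
    expect_equal(nrow(plan$specs), cs$n)
    rep <- coverage_report(plan)
    expect_true(rep$covered)
    expect_equal(rep$n_uncovered, 0L)
  }
  # coronal slabs vary along y only
  slab <- plan_grid(vols, c(91, 25, 91), c(1, 6, 1))
  expect_true(all(slab$specs$start_x == 0L))
  expect_true(all(slab$specs$start_z == 0L))
  expect_equal(length(unique(slab$specs$start_y)), 6L)
})

test_that("grid specs are sorted lexicographically by start", {
  plan <- plan_grid(c(91, 115, 91), c(48, 48, 48), c(2, 3, 2))
  s <- plan$specs
  ord <- order(s$start_x, s$start_y, s$start_z)
  expect_equal(ord, seq_len(nrow(s)))
})

test_that("ROI specs center, clamp, and validate", {
  specs <- roi_patch_specs(list(c(30, 57, 30), c(60, 57, 60)),
                           c(64, 64, 64), c(91, 115, 91))
  expect_equal(nrow(specs), 2L)
  expect_true(all(specs$start_x >= 0 & specs$start_x + 64 <= 91))
  expect_true(all(specs$start_y >= 0 & specs$start_y + 64 <= 115))

  corner <- roi_patch_specs(list(c(0, 0, 0)), c(8, 8, 8), c(20, 20, 20))
  expect_equal(unlist(corner[1, 1:3], use.names = FALSE), c(0L, 0L, 0L))

  whole <- roi_patch_specs(list(c(10, 10, 10)), c(21, 21, 21), c(21, 21, 21))
  expect_equal(unlist(whole[1, 1:3], use.names = FALSE), c(0L, 0L, 0L))

  expect_error(roi_patch_specs(list(c(30, 30, 30)), c(99, 8, 8),
                               c(91, 115, 91)), "exceeds")
  expect_error(roi_patch_specs(list(c(95, 10, 10)), c(8, 8, 8),
                               c(91, 115, 91)), "outside")
})

test_that("extraction slices exactly and leaves the input intact", {
  v <- rand_vol(c(12, 14, 12), seed = 11)
  before <- v$data
  plan <- plan_grid(c(12, 14, 12), c(8, 8, 8), c(2, 2, 2))
  patches <- extract_patches(v, plan)
  expect_identical(v$data, before)
  for (i in seq_len(nrow(plan$specs))) {
    s <- as.integer(unlist(plan$specs[i, 1:3]))
    expect_identical(patches[[i]]$data,
                     v$data[s[1] + 1:8, s[2] + 1:8, s[3] + 1:8])
    expect_equal(patches[[i]]$origin_offset, s)
  }
  # overlap regions byte-identical across patches
  p1 <- patches[[1]]$data; p2 <- patches[[2]]$data  # differ in z start only
  z0 <- plan$specs$start_z[2]
  expect_identical(p1[, , (z0 + 1):8], p2[, , 1:(8 - z0)])
})

test_that("a full covering plan touches every voxel value", {
  shape <- c(10, 12, 10)
  v <- vol3d(array(seq_len(prod(shape)), shape))
  plan <- plan_grid(shape, c(6, 6, 6), c(2, 3, 2))
  patches <- extract_patches(v, plan)
  seen <- sort(unique(unlist(lapply(patches, function(p) as.vector(p$data)))))
  expect_equal(seen, seq_len(prod(shape)))
})

test_that("out-of-bounds specs error with their index", {
  v <- rand_vol(c(8, 8, 8))
  bad <- tibble::tibble(start_x = c(0L, 4L), start_y = 0L, start_z = 0L,
                        size_x = 6L, size_y = 6L, size_z = 6L)
  expect_error(extract_patches(v, bad), "spec 2")
})

test_that("grid plans round-trip through JSON", {
  plan <- plan_grid(c(91, 115, 91), c(48, 48, 48), c(2, 3, 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_grid_plan(plan, path)
  plan2 <- read_grid_plan(path)
  expect_equal(plan2$specs, plan$specs)
  expect_equal(plan2$patch_shape, plan$patch_shape)
  expect_equal(plan2$counts, plan$counts)
})

test_that("the nonzero-fraction filter drops background patches", {
  shape <- c(10, 10, 10)
  arr <- array(0, shape)
  arr[1:5, , ] <- 1  # half the volume is empty
  plan <- plan_grid(shape, c(5, 10, 10), c(2, 1, 1),
                    min_nonzero_fraction = 0.5, volume = vol3d(arr))
  expect_equal(nrow(plan$specs), 1L)
  expect_equal(plan$specs$start_x, 0L)
})

test_that("Monte-Carlo mean distance is seeded, scaled, and calibrated", {
  # unit cube: the mean distance between two uniform points is 0.661707...
  est <- mean_pairwise_distance_mc(c(1, 1, 1), 1, n_samples = 3e5, seed = 42)
  expect_lt(abs(est$mean_mm - 0.661707), 4 * est$se_mm)

  # determinism and exact scale equivariance under a shared seed
  a <- mean_pairwise_distance_mc(c(5, 3, 2), 1, n_samples = 1e4, seed = 7)
  b <- mean_pairwise_distance_mc(c(5, 3, 2), 1, n_samples = 1e4, seed = 7)
  expect_identical(a$mean_mm, b$mean_mm)
  c2 <- mean_pairwise_distance_mc(c(5, 3, 2), 2, n_samples = 1e4, seed = 7)
  expect_equal(c2$mean_mm, 2 * a$mean_mm, tolerance = 1e-12)

  # degenerate segment of length a: mean |U - U'| * a = a / 3
  seg <- mean_pairwise_distance_mc(c(9, 0, 0), 1, n_samples = 2e5, seed = 8)
  expect_lt(abs(seg$mean_mm - 3), 4 * seg$se_mm)

  expect_error(mean_pairwise_distance_mc(c(0, 0, 0), 1, 10), "zero")
})
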