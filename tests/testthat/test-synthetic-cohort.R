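small_cfg <- function(...) {
  shape <- c(20, 24, 20)
  args <- utils::modifyList(
    list(n_subjects = 10, class_fraction_ad = 0.5, volume_shape = shape,
         atrophy_sites = list(list(center = c(7, 10, 7), radius = 4,
                                   delta = 0.4)),
         noise_sd = 0.05, background_smoothness_mm = 4, seed = 1),
    list(...)
  )
  do.call(cohort_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_subjects = 1), ">= 2")
  expect_error(small_cfg(noise_sd = -1), "nonnegative")
  expect_error(cohort_config(class_fraction_ad = 1), "\\(0, 1\\)")
  expect_error(
    cohort_config(volume_shape = c(20, 20, 20), atrophy_sites =
      list(list(center = c(100, 100, 100), radius = 3, delta = 0.3))),
    "outside"
  )
  expect_error(
    cohort_config(atrophy_sites =
      list(list(center = c(10, 10, 10), radius = 3, delta = 1.4))),
    "delta"
  )
})

test_that("cohorts have the configured size, labels, and readable volumes", {
  cfg <- cohort_config(n_subjects = 20, class_fraction_ad = 0.5,
                       volume_shape = c(16, 18, 16),
                       atrophy_sites = default_atrophy_sites(c(16, 18, 16)),
                       background_smoothness_mm = 4, seed = 0)
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cfg, dir = dir, keep_volumes = TRUE)
  expect_equal(sum(cohort$label == "AD"), 10L)
  expect_equal(sum(cohort$label == "CN"), 10L)
  expect_equal(anyDuplicated(cohort$subject_id), 0L)
  expect_true(all(file.exists(cohort$volume_path)))
  v <- read_volume(cohort$volume_path[1])
  expect_equal(dim(v), c(16L, 18L, 16L))
  expect_equal(v$voxel_size_mm, rep(1.5, 3))
})

test_that("generation is deterministic given the configuration", {
  a <- generate_cohort(small_cfg())
  b <- generate_cohort(small_cfg())
  va <- cohort_volumes(a); vb <- cohort_volumes(b)
  for (id in a$subject_id) expect_identical(va[[id]]$data, vb[[id]]$data)
  c2 <- generate_cohort(small_cfg(seed = 2))
  expect_false(identical(cohort_volumes(c2)[[1]]$data, va[[1]]$data))
})

test_that("intensities respect the stated bounds", {
  cohort <- generate_cohort(small_cfg(noise_sd = 0.1))
  for (v in cohort_volumes(cohort)) {
    expect_gte(min(v$data), 0)
    expect_lte(max(v$data), 1 + 5 * 0.1)
  }
})

test_that("atrophy reduces site intensity by the configured effect size", {
  # hard core of the sphere (radius - 2): the reduction is exactly 1 - delta
  # before noise; with n = 100 the Monte-Carlo error is small
  delta <- 0.4
  cfg <- cohort_config(
    n_subjects = 100, class_fraction_ad = 0.5, volume_shape = c(20, 24, 20),
    atrophy_sites = list(list(center = c(8, 12, 8), radius = 8,
                              delta = delta)),
    noise_sd = 0.05, background_smoothness_mm = 4, jitter_voxels = 0,
    seed = 3
  )
  cohort <- generate_cohort(cfg)
  vols <- cohort_volumes(cohort)
  ctr <- c(8, 12, 8); core_r <- 6
  idx <- expand.grid(x = 0:19, y = 0:23, z = 0:19)
  core <- with(idx, (x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2 <=
                 core_r^2)
  site_mean <- vapply(cohort$subject_id, function(id) {
    mean(vols[[id]]$data[as.matrix(idx[core, ]) + 1L])
  }, numeric(1))
  m_ad <- mean(site_mean[cohort$label == "AD"])
  m_cn <- mean(site_mean[cohort$label == "CN"])
  expect_lt(m_ad, m_cn)
  tmpl <- cohort_template(cfg)
  tmpl_mean <- mean(tmpl$data[as.matrix(idx[core, ]) + 1L])
  expect_equal(m_cn - m_ad, delta * tmpl_mean, tolerance = 0.05)
})

test_that("full heterogeneity spares the primary site in every AD subject", {
  cfg <- small_cfg(heterogeneity_fraction = 1)
  cohort <- generate_cohort(cfg)
  vols <- cohort_volumes(cohort)
  ctr <- c(7, 10, 7)
  site_mean <- vapply(cohort$subject_id, function(id) {
    mean(vols[[id]]$data[(ctr[1] - 1):(ctr[1] + 3),
                         (ctr[2] - 1):(ctr[2] + 3),
                         (ctr[3] - 1):(ctr[3] + 3)])
  }, numeric(1))
  m_ad <- mean(site_mean[cohort$label == "AD"])
  m_cn <- mean(site_mean[cohort$label == "CN"])
  # the only site is spared for everyone: classes differ only by noise
  expect_lt(abs(m_ad - m_cn), 0.05)
})

test_that("zero effect size makes the classes exchangeable", {
  cfg <- small_cfg()
  cfg$atrophy_sites[[1]]$delta <- 0
  cohort <- generate_cohort(cfg)
  vols <- cohort_volumes(cohort)
  overall <- vapply(cohort$subject_id,
                    function(id) mean(vols[[id]]$data), numeric(1))
  expect_lt(abs(mean(overall[cohort$label == "AD"]) -
                mean(overall[cohort$label == "CN"])), 0.02)
})

test_that("cohort tables round-trip and reject malformed input", {
  cohort <- generate_cohort(small_cfg())
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(cohort, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(cohort) + 1L)  # header + one row each
  back <- read_cohort_table(path)
  expect_equal(back, tibble::as_tibble(cohort[, c("subject_id", "label",
                                                  "volume_path", "split")]),
               ignore_attr = TRUE)

  dup <- cohort
  dup$subject_id[2] <- dup$subject_id[1]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(dup, path2)
  expect_error(read_cohort_table(path2), "duplicate subject_id.*row 2")

  bad <- cohort
  bad$label[3] <- "XX"
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(bad, path3)
  expect_error(read_cohort_table(path3), "row 3")

  expect_error(write_cohort_table(cohort[0, ], path), "non-empty")
})
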