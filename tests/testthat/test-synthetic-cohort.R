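test_that("cohort generation is deterministic and respects its spec", {
  g <- tiny_grid()
  spec <- cohort_spec(n_subjects = 4, seed = 11L)
  c1 <- generate_reference_cohort(spec, g)
  c2 <- generate_reference_cohort(spec, g)
  expect_identical(c1, c2)

  spec100 <- cohort_spec(n_subjects = 100, age_range = c(18, 77), seed = 2L)
  ages <- vapply(generate_reference_cohort(spec100, grid_spec(rep(8L, 3L), 16)),
                 `[[`, numeric(1), "age")
  expect_true(all(ages >= 18 & ages <= 77))

  # all randomness off: subjects of identical age/sex are identical
  spec0 <- cohort_spec(n_subjects = 2, age_range = c(60, 60), sex_ratio = 1,
                       subject_sd = 0, noise_sd = 0, seed = 3L)
  c0 <- generate_reference_cohort(spec0, g)
  expect_identical(c0[[1]]$volume, c0[[2]]$volume)

  expect_error(generate_reference_cohort(spec, grid_spec(c(7, 16, 16), 8)),
               "degenerate")
})

test_that("age slope lowers mean gray matter density in older subjects", {
  g <- tiny_grid()
  atlas <- region_atlas(g)
  spec <- cohort_spec(subject_sd = 0, noise_sd = 0, age_slope_amplitude = 0.003)
  young <- generate_patient_scan(20, "F", grid = g, atlas = atlas,
                                 cohort = spec, subject_sd = 0, noise_sd = 0)
  old <- generate_patient_scan(70, "F", grid = g, atlas = atlas,
                               cohort = spec, subject_sd = 0, noise_sd = 0)
  expect_lt(mean(old$volume[atlas$brain]), mean(young$volume[atlas$brain]))
})

test_that("repeat simulation adds calibrated smoothed noise", {
  st <- stratum_cohort(n = 1L)
  scan <- st$cohort[[1]]

  expect_identical(simulate_repeat(scan, 0)$volume, scan$volume)
  expect_equal(simulate_repeat(scan, 0)$condition, "repeat")

  r1 <- simulate_repeat(scan, 0.02, 8, seed = 1L)
  r2 <- simulate_repeat(scan, 0.02, 8, seed = 2L)
  expect_false(identical(r1$volume, r2$volume))
  expect_identical(r1$volume, simulate_repeat(scan, 0.02, 8, seed = 1L)$volume)

  # empirical SD of the difference over brain voxels matches repeat_sd (10%)
  diffs <- (r1$volume - scan$volume)[st$atlas$brain]
  expect_equal(sd(diffs), 0.02, tolerance = 0.10)
})

test_that("patient generation plants recoverable atrophy", {
  g <- tiny_grid()
  atlas <- region_atlas(g)
  spec <- cohort_spec(subject_sd = 0, noise_sd = 0)

  base <- generate_patient_scan(60, "M", grid = g, atlas = atlas,
                                cohort = spec, subject_sd = 0, noise_sd = 0)
  # noise off, no atrophy: equals the clipped mean model
  model <- mean_gm_model(60, "M", atlas)
  model[model < 0] <- 0
  expect_equal(base$volume, model)

  # zero effect leaves the region untouched voxel-for-voxel
  zero <- generate_patient_scan(60, "M", list(temporal = 0), g, atlas,
                                cohort = spec, subject_sd = 0, noise_sd = 0)
  expect_identical(zero$volume, base$volume)

  # positive effect reduces density exactly inside the region
  atro <- generate_patient_scan(60, "M", list(deep = 2), g, atlas,
                                cohort = spec, subject_sd = 0, noise_sd = 0)
  m <- atlas$labels$deep
  expect_true(all(atro$volume[m] <= base$volume[m]))
  expect_identical(atro$volume[!m], base$volume[!m])

  expect_error(generate_patient_scan(60, "M", list(amygdala = 2), g, atlas,
                                     cohort = spec), "unknown region")
})

test_that("smooth noise fields hit their target point SD", {
  g <- grid_spec(c(24L, 24L, 24L), 4)
  f <- smooth_noise_field(g, sd = 0.05, fwhm_mm = 8, seed = 9L)
  inner <- f[5:20, 5:20, 5:20]  # interior, away from the zero boundary
  expect_equal(sd(as.vector(inner)), 0.05, tolerance = 0.10)
  expect_equal(mean(inner), 0, tolerance = 0.01)
  expect_identical(f, smooth_noise_field(g, 0.05, 8, seed = 9L))
})
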