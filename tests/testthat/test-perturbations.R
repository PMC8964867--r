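test_that("identity perturbation leaves the volume bit-identical", {
  st <- stratum_cohort(n = 1L, grid = tiny_grid())
  scan <- st$cohort[[1]]
  ident <- perturbation_spec("identity")
  out <- apply_perturbation(scan, ident, st$atlas)
  expect_identical(out$volume, scan$volume)
  expect_equal(out$condition, "perturbed:identity")
})

test_that("failure probability produces typed failure signals", {
  st <- stratum_cohort(n = 2L, grid = tiny_grid())
  always <- perturbation_spec("broken", failure_prob = 1)
  for (s in st$cohort) {
    out <- apply_perturbation(s, always, st$atlas)
    expect_true(is_perturbation_failure(out))
    expect_equal(out$name, "broken")
  }
  never <- perturbation_spec("solid", failure_prob = 0)
  expect_false(is_perturbation_failure(
    apply_perturbation(st$cohort[[1]], never, st$atlas)))
})

test_that("perturbation operators act as specified", {
  st <- stratum_cohort(n = 1L, grid = tiny_grid())
  scan <- st$cohort[[1]]
  atlas <- st$atlas

  # global scaling multiplies densities
  sc <- apply_perturbation(scan, perturbation_spec("gs", global_scale = 1.5),
                           atlas)
  expect_equal(sc$volume, scan$volume * 1.5)

  # bias field peaks at its centre and decays with distance
  b <- apply_perturbation(
    scan, perturbation_spec("bias", bias_amplitude = 0.1,
                            bias_center = "deep", bias_decay = 10), atlas)
  added <- b$volume - scan$volume
  expect_gte(min(added), 0)
  centre_vox <- round(atrophyz:::region_centroid(atlas, "deep") /
                        atlas$grid$voxel_size + 0.5)
  expect_equal(added[centre_vox[1], centre_vox[2], centre_vox[3]], 0.1,
               tolerance = 0.2)
  expect_lt(added[1, 1, 1], 1e-6)

  # erosion reduces density only inside its region
  er <- apply_perturbation(
    scan, perturbation_spec("er", erosion_region = "deep",
                            erosion_frac = 0.5), atlas)
  m <- atlas$labels$deep
  expect_equal(er$volume[m], scan$volume[m] * 0.5)
  expect_identical(er$volume[!m], scan$volume[!m])

  # sub-voxel jitter changes the volume but preserves it approximately
  j <- apply_perturbation(scan, perturbation_spec("jit", jitter_mm = 2), atlas)
  expect_false(identical(j$volume, scan$volume))
  expect_equal(mean(j$volume), mean(scan$volume), tolerance = 0.05)
})

test_that("trilinear translation is exact for integer-voxel shifts", {
  v <- array(0, dim = c(8, 8, 8))
  v[4, 4, 4] <- 1
  out <- atrophyz:::translate_trilinear(v, c(1, 0, 0))
  expect_equal(out[5, 4, 4], 1)
  expect_equal(sum(out), 1)
  half <- atrophyz:::translate_trilinear(v, c(0.5, 0, 0))
  expect_equal(half[4, 4, 4], 0.5)
  expect_equal(half[5, 4, 4], 0.5)
})
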