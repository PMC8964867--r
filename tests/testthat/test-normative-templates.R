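make_flat_scan <- function(value, age, sex, id, grid) {
  subject_scan(array(value, dim = grid$shape), age, sex, id, grid = grid)
}

test_that("reference selection uses a closed, sex-specific age window", {
  g <- grid_spec(rep(8L, 3L), 16)
  ages <- c(60, 61, 62, 63, 64, 65)
  cohort <- lapply(seq_along(ages), function(i)
    make_flat_scan(0.5, ages[i], "F", paste0("s", i), g))

  sel <- select_reference_subjects(cohort, "F", 63, 2)
  expect_setequal(vapply(sel, `[[`, numeric(1), "age"), c(61, 62, 63, 64, 65))

  # window 0 with no exact match is empty
  expect_length(select_reference_subjects(cohort, "F", 63.5, 0), 0)

  # sex filter excludes the other sex entirely
  mixed <- c(cohort, list(make_flat_scan(0.5, 63, "M", "m1", g)))
  selF <- select_reference_subjects(mixed, "F", 63, 2)
  expect_false(any(vapply(selF, `[[`, character(1), "sex") == "M"))

  # enlarging the window never decreases the selection
  for (w in c(0, 1, 2, 5)) {
    n_small <- length(select_reference_subjects(cohort, "F", 63, w))
    n_large <- length(select_reference_subjects(cohort, "F", 63, w + 1))
    expect_gte(n_large, n_small)
  }
})

test_that("templates hold the voxel-wise mean and sample SD", {
  g <- grid_spec(rep(8L, 3L), 16)
  two <- list(make_flat_scan(1, 60, "F", "a", g),
              make_flat_scan(3, 60, "F", "b", g))
  tpl <- build_template(two, "F", 60, 2, min_n = 2)
  expect_equal(tpl$mean_map, array(2, dim = g$shape))
  expect_equal(tpl$sd_map, array(sqrt(2), dim = g$shape))
  expect_equal(tpl$n_ref, 2L)

  # identical subjects give an exactly zero SD map
  same <- list(make_flat_scan(0.7, 60, "F", "a", g),
               make_flat_scan(0.7, 60, "F", "b", g))
  expect_true(all(build_template(same, "F", 60, 2, 2)$sd_map == 0))

  # degenerate strata are rejected
  expect_error(build_template(two[1], "F", 60, 2, min_n = 1), "n=1")
  expect_error(build_template(two, "F", 60, 2, min_n = 10), "min_n")
  expect_error(build_template(list(), "F", 60, 2), "n=0")
})

test_that("template estimates match a brute-force oracle and are order-invariant", {
  g <- grid_spec(rep(8L, 3L), 16)
  set.seed(41)
  n <- 7L
  scans <- lapply(seq_len(n), function(i)
    subject_scan(array(runif(prod(g$shape), 0.1, 1), dim = g$shape),
                 60 + i / 10, "F", paste0("s", i), grid = g))
  tpl <- build_template(scans, "F", 60, 2, min_n = n)

  # independent loop-based two-pass computation at a handful of voxels
  set.seed(42)
  for (v in sample(prod(g$shape), 25)) {
    xs <- vapply(scans, function(s) s$volume[v], numeric(1))
    mu <- sum(xs) / n
    ss <- 0
    for (x in xs) ss <- ss + (x - mu)^2
    expect_equal(tpl$mean_map[v], mu, tolerance = 1e-10)
    expect_equal(tpl$sd_map[v], sqrt(ss / (n - 1)), tolerance = 1e-10)
  }

  perm <- build_template(rev(scans), "F", 60, 2, min_n = n)
  expect_equal(perm$mean_map, tpl$mean_map)
  expect_equal(perm$sd_map, tpl$sd_map)
})

test_that("the gray-matter mask respects thresholds and brain geometry", {
  st <- stratum_cohort(n = 20L, grid = tiny_grid())
  tpl <- build_template(st$cohort, "F", 65, 2, min_n = 10)

  expect_error(derive_gm_mask(tpl, mean_threshold = max(tpl$mean_map) + 1),
               "empty")

  m0 <- derive_gm_mask(tpl, mean_threshold = 0, sd_floor = 0)
  expect_equal(m0$mask, tpl$mean_map > 0 & tpl$sd_map > 0)

  mask <- derive_gm_mask(tpl, 0.1, 1e-6)
  expect_true(all(st$atlas$brain[mask$mask]))  # mask inside the ellipsoid
  expect_gt(mask$n_voxels, 0)
  expect_equal(mask$provenance$mean_threshold, 0.1)
})
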