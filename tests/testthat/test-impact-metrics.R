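test_that("RMSE matches hand calculations and is symmetric", {
  tpl <- toy_template(n_active = 3L)
  mask <- derive_gm_mask(tpl)
  za <- zscore_map(toy_scan(c(1, 2, 3), tpl), tpl, mask)
  zb <- zscore_map(toy_scan(c(1, 2, 5), tpl), tpl, mask)

  expect_equal(zmap_rmse(za, zb, mask), sqrt(4 / 3))
  expect_equal(zmap_rmse(zb, za, mask), zmap_rmse(za, zb, mask))
  expect_equal(zmap_rmse(za, za, mask), 0)
})

test_that("RMSE scales linearly with the difference magnitude", {
  tpl <- toy_template(n_active = 20L)
  mask <- derive_gm_mask(tpl)
  set.seed(5)
  z0 <- 0.5 * rnorm(20)
  dz <- 0.3 * rnorm(20)
  base <- zmap_rmse(zscore_map(toy_scan(z0 + dz, tpl), tpl, mask),
                    zscore_map(toy_scan(z0, tpl), tpl, mask), mask)
  for (c in c(0.5, 2, 7)) {
    scaled <- zmap_rmse(zscore_map(toy_scan(z0 + c * dz, tpl), tpl, mask),
                        zscore_map(toy_scan(z0, tpl), tpl, mask), mask)
    expect_equal(scaled, c * base, tolerance = 1e-12)
  }
})

test_that("RMSE rejects mismatched masks and grids", {
  tpl <- toy_template(n_active = 3L)
  mask <- derive_gm_mask(tpl)
  big <- derive_gm_mask(toy_template(n_active = 5L))
  za <- zscore_map(toy_scan(c(1, 2, 3), tpl), tpl, mask)
  expect_error(zmap_rmse(za, za, big), "not defined on every mask voxel")
})

test_that("deviation maps aggregate signed or absolute differences", {
  tpl <- toy_template(n_active = 2L)
  mask <- derive_gm_mask(tpl)
  zm <- function(z) zscore_map(toy_scan(z, tpl), tpl, mask)

  # identical pairs give the zero map
  d0 <- deviation_map(list(list(zm(c(1, 1)), zm(c(1, 1)))), mask)
  expect_true(all(d0$map[mask$mask] == 0))

  # one pair with dz = +2 at one voxel
  d1 <- deviation_map(list(list(zm(c(2, 0)), zm(c(0, 0)))), mask)
  expect_equal(d1$map[mask$mask], c(2, 0))

  # +2 and -2 cancel under the signed-mean convention, not under mean-abs
  pairs <- list(list(zm(c(2, 0)), zm(c(0, 0))),
                list(zm(c(-2, 0)), zm(c(0, 0))))
  expect_equal(deviation_map(pairs, mask)$map[mask$mask], c(0, 0))
  expect_equal(deviation_map(pairs, mask, method = "mean_abs")$map[mask$mask],
               c(2, 0))
  expect_error(deviation_map(list(), mask), "at least one pair")
})

test_that("RMSE summaries report Table-2-style statistics", {
  recs <- rbind(impact_record("a", "fullface", "perturbed:x", 0.1),
                impact_record("b", "fullface", "perturbed:x", 0.3))
  s <- summarize_rmse(recs)
  expect_equal(s$mean, 0.2)
  expect_equal(s$min, 0.1)
  expect_equal(s$max, 0.3)
  expect_equal(s$n_failed, 0)

  single <- summarize_rmse(impact_record("a", "f", "p", 0.5))
  expect_equal(single$mean, 0.5)
  expect_equal(single$min, single$max)
  expect_equal(single$sd, 0)
  expect_false(single$sd_defined)

  mixed <- rbind(impact_record("a", "f", "p", 0.4),
                 impact_record("b", "f", "p", status = "failed:perturbation"))
  sm <- summarize_rmse(mixed)
  expect_equal(sm$n_failed, 1)
  expect_equal(sm$n_ok, 1)
  expect_equal(sm$mean, 0.4)

  all_failed <- impact_record("a", "f", "p", status = "failed:perturbation")
  expect_error(summarize_rmse(all_failed), "no ok records")
})
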