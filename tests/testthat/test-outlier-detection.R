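test_that("Grubbs statistic matches hand evaluations", {
  g1 <- grubbs_statistic(c(-1, 0, 1))
  expect_equal(g1$G, 1)
  expect_true(g1$candidate_index %in% c(1L, 3L))

  g2 <- grubbs_statistic(c(0, 0, 0, 10))
  expect_equal(g2$G, 1.5)  # mean 2.5, sd 5, max dev 7.5
  expect_equal(g2$candidate_index, 4L)

  expect_error(grubbs_statistic(c(1, 1, 1)), "zero SD")
  expect_error(grubbs_statistic(c(1, 2)), "at least 3")
  # ties at the maximum deviation resolve to the lowest index
  expect_equal(grubbs_statistic(c(5, 0, 0, 0, 5))$candidate_index, 1L)
})

test_that("critical values follow the two-sided t-based formula", {
  expect_equal(grubbs_critical(3, 0.05), 1.1543, tolerance = 1e-4)

  # alpha down, critical value up; n up, critical value up
  expect_gt(grubbs_critical(10, 0.01), grubbs_critical(10, 0.05))
  expect_gt(grubbs_critical(10, 0.05), grubbs_critical(3, 0.05))

  expect_error(grubbs_critical(2, 0.05))
  expect_error(grubbs_critical(10, 0))
})

test_that("iterative Grubbs removes planted outliers then stops", {
  set.seed(101)
  x <- rnorm(50)
  x[17] <- 10 * sd(x[-17])
  rep1 <- iterative_grubbs(x, 0.05)
  expect_equal(rep1$flagged_ids[1], 17L)

  # idempotence: the cleaned sample yields no further outliers
  cleaned <- x[-match(rep1$flagged_ids, seq_along(x))]
  expect_equal(iterative_grubbs(cleaned, 0.05)$n_flagged, 0L)

  # custom ids are propagated in removal order
  ids <- sprintf("s%02d", seq_along(x))
  expect_equal(iterative_grubbs(x, 0.05, ids = ids)$flagged_ids[1], "s17")

  # constant data: nothing can be flagged
  expect_equal(iterative_grubbs(rep(1, 10))$n_flagged, 0L)

  # below the n >= 3 floor: empty report with a warning status
  expect_warning(r <- iterative_grubbs(c(1, 2)), "fewer than 3")
  expect_equal(r$status, "insufficient_n")
  expect_equal(r$n_flagged, 0L)
})

test_that("iterative Grubbs is location/scale invariant", {
  set.seed(7)
  x <- c(rnorm(30), 8, -9)
  base <- iterative_grubbs(x, 0.05)$flagged_ids
  expect_gt(length(base), 0)
  for (tr in list(c(3, 0), c(0.01, -5), c(250, 1e4))) {
    y <- tr[1] * x + tr[2]
    expect_equal(iterative_grubbs(y, 0.05)$flagged_ids, base)
  }
})

test_that("benchmark percentile criterion uses a strict threshold", {
  # 75th percentile of {1,2,3,4} is 3.25 under linear interpolation
  r <- benchmark_outliers(c(3.26, 5), benchmark = c(1, 2, 3, 4))
  expect_equal(r$n_flagged, 2L)
  expect_equal(r$parameters$threshold, 3.25)

  # a value exactly at the threshold is not flagged ("higher than")
  expect_equal(benchmark_outliers(c(0.5, 3.25), c(1, 2, 3, 4))$n_flagged, 0L)
  expect_equal(benchmark_outliers(c(1, 2), c(1, 2, 3, 4))$n_flagged, 0L)
  expect_error(benchmark_outliers(c(1), numeric(0)), "empty benchmark")

  # data.frame records: failures are not assessed
  recs <- rbind(impact_record("a", "f", "p", 5),
                impact_record("b", "f", "p", status = "failed:perturbation"))
  rb <- benchmark_outliers(recs, c(1, 2, 3, 4))
  expect_equal(rb$flagged_ids, "a")
  expect_equal(rb$n_total, 1L)
})
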