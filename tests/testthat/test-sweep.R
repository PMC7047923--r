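base_design <- function(covariance = cov_spec("ar1", sigma = 1, rho = 0.7)) {
  make_design(n_control = 6, n_treat = 6, control_mean = 2,
              covariance = covariance,
              trend = trend_spec("L_up", beta = 1, ip = 3),
              num_timepoints = 6, t_interval = c(0, 6))
}

paper_grid <- list(sigma = c(1, 2, 4), n_per_group = c(10, 20, 50),
                   q = c(3, 6, 12))

test_that("scheduled repetitions multiply out the factorial grid", {
  cfg <- sweep_config(grids = paper_grid, repetitions = 100,
                      base_design = base_design(), seed = 1)
  expect_equal(scheduled_repetitions(cfg), 2700)
  cfg2 <- sweep_config(grids = paper_grid, repetitions = 2,
                       base_design = base_design(), seed = 1)
  expect_equal(scheduled_repetitions(cfg2), 54)
})

test_that("run_sweep produces one row per scheduled repetition", {
  cfg <- sweep_config(grids = list(sigma = c(1, 2)), repetitions = 3,
                      base_design = base_design(), detector = "oracle",
                      seed = 4)
  res <- run_sweep(cfg)
  expect_equal(nrow(res), 6)
  expect_setequal(unique(res$sigma), c(1, 2))
  expect_equal(unname(table(res$sigma)), rep(3L, 2), ignore_attr = TRUE)

  single <- sweep_config(grids = list(sigma = 1), repetitions = 1,
                         base_design = base_design(), seed = 4)
  expect_equal(nrow(run_sweep(single)), 1)
})

test_that("the perfect oracle scores sensitivity 1 on every differential form", {
  trends <- list(
    linear_inc = trend_spec("linear", beta = c(0, 1)),
    quadratic = trend_spec("quadratic", beta = c(0, 3, -0.5)),
    oscillating = trend_spec("oscillating_M", beta = c(0, 2), ip = c(1.5, 3, 4.5)),
    hockey_up = trend_spec("L_up", beta = 1, ip = 3),
    hockey_down = trend_spec("L_down", beta = c(2, -0.5)),
    null = trend_spec("none")
  )
  cfg <- sweep_config(grids = list(sigma = 1), repetitions = 5,
                      base_design = base_design(), trends = trends,
                      detector = "oracle", seed = 12)
  res <- run_sweep(cfg)
  summ <- summarize_sweep(res)
  diff_rows <- summ$form != "null"
  expect_true(all(summ$sensitivity[diff_rows] == 1))
  expect_equal(summ$specificity[summ$form == "null"], 1)
  # oracle recovers the truth exactly (cosine to numerical precision)
  expect_equal(res$cosine[res$truth_is_diff],
               rep(1, sum(res$truth_is_diff)))
  expect_true(all(res$euclidean[res$truth_is_diff] == 0))
  expect_true(all(res$norm_euclidean[res$truth_is_diff] == 0))
  expect_true(all(!res$estimate_missing))
  expect_equal(summ$non_missing, summ$repetitions)
})

test_that("sweeps are reproducible and independent of setting order", {
  cfg <- sweep_config(grids = list(sigma = c(1, 2), n_per_group = c(5, 10)),
                      repetitions = 2, base_design = base_design(),
                      detector = "ttest", seed = 8)
  expect_identical(run_sweep(cfg), run_sweep(cfg))
})

test_that("detector failures are flagged as missing estimates, not dropped", {
  failing <- function(dataset, truth) stop("no estimate")
  cfg <- sweep_config(grids = list(sigma = 1), repetitions = 4,
                      base_design = base_design(), detector = failing,
                      seed = 2)
  res <- run_sweep(cfg)
  expect_equal(nrow(res), 4)
  expect_true(all(res$estimate_missing))
  expect_true(all(is.na(res$detected)))
  summ <- summarize_sweep(res)
  expect_equal(summ$repetitions, 4)
  expect_equal(summ$non_missing, 0)
  expect_true(is.na(summ$sensitivity))
})

test_that("summaries report explicit denominators per group", {
  # synthetic results table: 10 scheduled, 7 usable, 5 detected
  res <- data.frame(
    form = "linear", sigma = 1, rep = 1:10,
    truth_is_diff = TRUE,
    detected = c(rep(TRUE, 5), rep(FALSE, 2), rep(NA, 3)),
    estimate_missing = c(rep(FALSE, 7), rep(TRUE, 3)),
    cosine = c(rep(0.9, 7), rep(NA, 3)),
    euclidean = c(rep(1.5, 7), rep(NA, 3)),
    norm_euclidean = c(rep(0.2, 7), rep(NA, 3))
  )
  summ <- summarize_sweep(res)
  expect_equal(summ$repetitions, 10)
  expect_equal(summ$non_missing, 7)
  expect_equal(summ$sensitivity, 5 / 7)
  expect_equal(summ$avg_cosine, 0.9)
  expect_equal(summ$avg_euclidean, 1.5)
})

test_that("the t-test detector attains high power on a strong signal", {
  cfg <- sweep_config(grids = list(n_per_group = 25), repetitions = 10,
                      base_design = base_design(
                        covariance = cov_spec("ar1", sigma = 0.5, rho = 0.3)),
                      trends = list(strong = trend_spec("linear", beta = c(0, 2)),
                                    null = trend_spec("none")),
                      detector = "ttest", seed = 21)
  res <- run_sweep(cfg)
  summ <- summarize_sweep(res)
  expect_equal(summ$sensitivity[summ$form == "strong"], 1)
  expect_gte(summ$specificity[summ$form == "null"], 0.8)
  # t-test estimates point the right way
  expect_true(all(res$cosine[res$form == "strong"] > 0.9))
})

test_that("malformed sweep configs are rejected", {
  expect_error(sweep_config(grids = list(), repetitions = 2,
                            base_design = base_design()), "non-empty")
  expect_error(sweep_config(grids = list(bogus = 1:2), repetitions = 2,
                            base_design = base_design()), "unknown grid")
  expect_error(sweep_config(grids = list(sigma = 1), repetitions = 0,
                            base_design = base_design()), ">= 1")
  expect_error(get_detector("nope"), "unknown detector")
})
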