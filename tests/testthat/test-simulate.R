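test_that("equidistant schedules span the interval inclusively", {
  d <- make_design(num_timepoints = 5, t_interval = c(0, 10))
  times <- make_timepoints(d)
  expect_length(times, 20)
  expect_equal(times[[1]], c(0, 2.5, 5, 7.5, 10))
  expect_true(all(vapply(times, identical, logical(1), times[[1]])))

  d2 <- make_design(num_timepoints = 7, t_interval = c(0, 6))
  expect_equal(make_timepoints(d2)[[1]], 0:6)
})

test_that("asynchronous schedules keep a fixed baseline and stay sorted", {
  d <- make_design(num_timepoints = 6, t_interval = c(0, 10),
                   asynch_time = TRUE, seed = 55)
  set.seed(55)
  times <- make_timepoints(d)
  for (ti in times) {
    expect_equal(ti[1], 0)
    expect_false(is.unsorted(ti))
    expect_true(all(ti >= 0 & ti <= 10))
    expect_length(ti, 6)
  }
  # subjects differ from one another
  expect_gt(length(unique(vapply(times, paste, character(1), collapse = ","))),
            1)
})

test_that("mean vector is mu0 for controls and mu0 + f(t) for treatment", {
  d <- make_design(n_control = 3, n_treat = 2, control_mean = 2,
                   trend = trend_spec("L_up", beta = 0.5, ip = 5),
                   num_timepoints = 5, t_interval = c(0, 10))
  times <- make_timepoints(d)
  mu <- build_mean_vector(d, times)
  expect_length(mu$mu, 25)
  expect_equal(mu$blocks[[1]], rep(2, 5))
  expect_equal(mu$blocks[[4]], 2 + c(0, 0, 0, 0.5 * 2.5, 0.5 * 5))
  # treatment at t = 9 under this trend: 2 + 0.5 * (9 - 5) = 4
  expect_equal(2 + evaluate_trend(d$trend, 9, t_interval = c(0, 10)), 4)

  d_null <- make_design(n_control = 3, n_treat = 2, control_mean = 2,
                        trend = trend_spec("none"),
                        num_timepoints = 5, t_interval = c(0, 10))
  expect_equal(build_mean_vector(d_null, times)$mu, rep(2, 25))
})

test_that("simulate_feature composes the full pipeline", {
  d <- make_design(n_control = 20, n_treat = 20, num_timepoints = 7,
                   t_interval = c(0, 6), seed = 77)
  sim <- simulate_feature(d)
  expect_s3_class(sim, "sim_feature")
  expect_equal(nrow(sim$records), 280)
  expect_equal(sim$n_total, 280)
  expect_equal(names(sim$records), c("Y", "ID", "time", "group", "Y_obs"))
  # control IDs first, then treatment; records sorted by ID then time
  expect_equal(unique(sim$records$ID[sim$records$group == "Control"]), 1:20)
  expect_equal(unique(sim$records$ID[sim$records$group == "Treatment"]), 21:40)
  expect_false(is.unsorted(sim$records$ID))
  expect_equal(sum(sim$records$group == "Control"), 140)
  # no missingness requested
  expect_equal(nrow(sim$miss_data), 0)
  expect_identical(sim$records$Y, sim$records$Y_obs)
  # mean/covariance returned with matching dimensions
  expect_length(sim$mu, 280)
  expect_equal(attr(sim$sigma, "n_total"), 280)
})

test_that("same seed reproduces the dataset exactly", {
  d <- make_design(seed = 99, asynch_time = TRUE, missing_pct = 0.2,
                   missing_per_subject = 2, miss_val = 0)
  expect_identical(simulate_feature(d), simulate_feature(d))
})

test_that("missingness accounting is exact and spares the baseline", {
  d <- make_design(n_control = 20, n_treat = 20, num_timepoints = 7,
                   t_interval = c(0, 6), missing_pct = 0.2,
                   missing_per_subject = 2, miss_val = 0, seed = 31)
  sim <- simulate_feature(d)
  # round(0.2 * 40) = 8 subjects, 2 cells each
  expect_equal(length(unique(sim$miss_data$miss_id)), 8)
  expect_equal(nrow(sim$miss_data), 16)
  expect_equal(as.vector(table(sim$miss_data$miss_id)), rep(2L, 8))
  expect_true(all(sim$miss_data$miss_time != 0))  # baseline excluded
  # Y_obs differs from Y on exactly the listed cells, imputed with miss_val
  differs <- sim$records$Y != sim$records$Y_obs
  expect_equal(sum(differs), 16)
  key_rec <- paste(sim$records$ID[differs], sim$records$time[differs])
  key_miss <- paste(sim$miss_data$miss_id, sim$miss_data$miss_time)
  expect_setequal(key_rec, key_miss)
  expect_true(all(sim$records$Y_obs[differs] == 0))
})

test_that("NA miss_val marks cells as not available", {
  d <- make_design(missing_pct = 0.5, missing_per_subject = 1,
                   miss_val = NA_real_, seed = 5)
  sim <- simulate_feature(d)
  expect_equal(sum(is.na(sim$records$Y_obs)), nrow(sim$miss_data))
  expect_false(anyNA(sim$records$Y))
})

test_that("missing_per_subject beyond q - 1 is rejected", {
  expect_error(make_design(num_timepoints = 4, missing_pct = 0.5,
                           missing_per_subject = 4),
               "baseline")
})

test_that("moment recovery: group mean difference converges to f(t)", {
  # truncation inactive at mu0 = 10; n = 500 per arm
  n <- 500; q <- 6
  trend <- trend_spec("L_up", beta = 0.5, ip = 2)
  d <- make_design(n_control = n, n_treat = n, control_mean = 10,
                   covariance = cov_spec("ar1", sigma = 1, rho = 0.7),
                   trend = trend, num_timepoints = q, t_interval = c(0, 5),
                   seed = 2024)
  sim <- simulate_feature(d)
  expect_equal(unique(sim$modes), "rejection")
  grid <- 0:5
  f_true <- evaluate_trend(trend, grid)
  rec <- sim$records
  for (j in seq_along(grid)) {
    at <- rec[rec$time == grid[j], ]
    diff_j <- mean(at$Y[at$group == "Treatment"]) -
      mean(at$Y[at$group == "Control"])
    se <- sqrt(2 / n)
    expect_lt(abs(diff_j - f_true[j]), 3 * se)
  }
  # pooled SD recovers sigma
  resid <- rec$Y - sim$mu
  expect_lt(abs(sd(resid) - 1), 3 / sqrt(2 * length(resid)))
})

test_that("community tables have the documented layout", {
  d <- make_design(n_control = 20, n_treat = 20,
                   trend = trend_spec("L_down", beta = c(2, -0.5)),
                   num_timepoints = 5, t_interval = c(0, 10),
                   missing_pct = 0.2, missing_per_subject = 2, miss_val = 0,
                   seed = 61)
  comm <- simulate_community(10, 4, d)
  expect_equal(dim(comm$abundance), c(10, 200))
  expect_equal(rownames(comm$abundance),
               c(paste0("Diff_Bug", 1:4), paste0("NoDiffBug_", 1:6)))
  expect_equal(comm$sample_meta$Sample_ID, paste0("Sample_", 1:200))
  expect_equal(colnames(comm$abundance), comm$sample_meta$Sample_ID)
  expect_equal(nrow(comm$sample_meta), ncol(comm$abundance))
  # metadata ordered by ID then time
  expect_false(is.unsorted(comm$sample_meta$ID))
  expect_equal(comm$sample_meta$time[1:5], c(0, 2.5, 5, 7.5, 10))

  # all-null and all-diff naming
  expect_true(all(startsWith(rownames(simulate_community(3, 0, d)$abundance),
                             "NoDiffBug")))
  expect_true(all(startsWith(rownames(simulate_community(3, 3, d)$abundance),
                             "Diff_Bug")))
})

test_that("diff features separate groups at late times, null features do not", {
  d <- make_design(n_control = 40, n_treat = 40, control_mean = 10,
                   trend = trend_spec("L_down", beta = c(2, -0.5)),
                   num_timepoints = 5, t_interval = c(0, 10), seed = 17)
  comm <- simulate_community(6, 3, d)
  meta <- comm$sample_meta
  early <- meta$time == 0
  gap_at <- function(row, sel) {
    mean(comm$abundance[row, sel & meta$group == "Treatment"]) -
      mean(comm$abundance[row, sel & meta$group == "Control"])
  }
  # under L_down(2, -0.5) the gap is 2 at t = 0 and 0 for t >= 4
  expect_gt(mean(vapply(1:3, gap_at, numeric(1), early)), 1)
  expect_lt(abs(mean(vapply(4:6, gap_at, numeric(1), early))), 1)
})

test_that("feature means are stable under reseeding", {
  d <- make_design(n_control = 30, n_treat = 30, control_mean = 10,
                   trend = trend_spec("linear", beta = c(0, 0.5)),
                   num_timepoints = 4, t_interval = c(0, 3))
  seeds <- 1:40
  means <- vapply(seeds, function(s) {
    d$seed <- s
    mean(simulate_community(2, 1, d)$abundance[1, ])
  }, numeric(1))
  analytic <- mean(build_mean_vector(d, make_timepoints(d))$mu)
  # variance of one feature mean under compound correlation:
  # (sigma^2 / N) * (1 + (q - 1) * rho)
  se_feature <- sqrt((1 + 3 * 0.7) / 240)
  expect_lt(abs(mean(means) - analytic), 3 * se_feature / sqrt(length(seeds)))
})

test_that("design-driven simulation replicates subjects with groups preserved", {
  sd_tbl <- data.frame(
    ID = rep(1:12, each = 4),
    time = rep(c(0, 3, 7, 12), 12),
    group = rep(c("Control", "Treatment"), each = 24)
  )
  sim <- simulate_from_design(sd_tbl, replication_factor = 5,
                              control_mean = 2,
                              covariance = cov_spec("ar1", 1, 0.7),
                              trend = trend_spec("L_up", beta = 0.5, ip = 5),
                              seed = 33)
  expect_equal(length(unique(sim$records$ID)), 60)
  expect_equal(sum(table(sim$records$ID, sim$records$group)[, "Control"] > 0),
               30)
  expect_equal(nrow(sim$records), 240)

  # factor 1 preserves subject count and time vectors
  sim1 <- simulate_from_design(sd_tbl, replication_factor = 1,
                               control_mean = 2,
                               covariance = cov_spec("ar1", 1, 0.7),
                               trend = trend_spec("none"), seed = 34)
  expect_equal(length(unique(sim1$records$ID)), 12)
  expect_equal(sim1$records$time[sim1$records$ID == 1], c(0, 3, 7, 12))
})

test_that("design-driven simulation handles unequal visit counts", {
  sd_tbl <- data.frame(
    ID = c(1, 1, 2, 2, 2, 3, 3, 3, 3),
    time = c(0, 2, 0, 1, 4, 0, 1, 2, 3),
    group = c("Control", "Control", "Control", "Control", "Control",
              "Treatment", "Treatment", "Treatment", "Treatment")
  )
  sim <- simulate_from_design(sd_tbl, replication_factor = 2,
                              control_mean = 5,
                              covariance = cov_spec("compound", 1, 0.3),
                              trend = trend_spec("linear", beta = c(0, 1)),
                              seed = 35)
  expect_equal(nrow(sim$records), 2 * (2 + 3 + 4))
  expect_equal(sim$n_total, 18)
  expect_error(simulate_from_design(sd_tbl[0, ], 1, 2,
                                    cov_spec("ar1"), trend_spec("none")),
               "non-empty")
})
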