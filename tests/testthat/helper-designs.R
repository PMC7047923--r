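# Shared design builders for the test suite.

make_design <- function(n_control = 10, n_treat = 10, control_mean = 2,
                        covariance = cov_spec("compound", sigma = 1, rho = 0.7),
                        trend = trend_spec("quadratic", beta = c(0, 3, -0.5)),
                        num_timepoints = 7, t_interval = c(0, 6),
                        asynch_time = FALSE, missing_pct = 0,
                        missing_per_subject = 0, miss_val = NA_real_,
                        truncation = truncation_spec(), seed = 101) {
  sim_design(n_control = n_control, n_treat = n_treat,
             control_mean = control_mean, covariance = covariance,
             trend = trend, num_timepoints = num_timepoints,
             t_interval = t_interval, asynch_time = asynch_time,
             missing_pct = missing_pct,
             missing_per_subject = missing_per_subject,
             miss_val = miss_val, truncation = truncation, seed = seed)
}

# trend evaluated by brute-force scalar arithmetic, independent of the
# vectorized implementation
oracle_poly <- function(beta, t) {
  vapply(t, function(ti) sum(beta * ti^(seq_along(beta) - 1L)), numeric(1))
}
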