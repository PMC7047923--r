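# longdasim

Simulation of longitudinal differential abundance for microbiome features,
plus a benchmarking harness for trend-recovery methods.

## The problem

Longitudinal microbiome studies ask when — not just whether — a taxon's
abundance differs between two groups. Methods that estimate time intervals of
differential abundance need validation data where the truth is known, and
study planners need to gauge how sample size, collection schedule, and
signal-to-noise affect detection before sequencing anything. `longdasim`
generates that data and scores estimators against the known truth.

## The model

A single (variance-stabilized) feature is drawn from a multivariate normal

    Y ~ N(mu, Sigma),        N = sum_i q_i observations

over n = n0 + n1 subjects with q_i repeated measurements each. The control
arm has constant mean mu0; the treatment arm has mean mu0 + f(t), where the
trend f is chosen from:

* polynomials: f(t) = beta0 + beta1 t + ... + betap t^p, p <= 3;
* hockey sticks: `L_up`, zero before an inflection point IP then slope
  beta1 (t − IP); `L_down`, beta0 + beta1 t down to zero at the implied
  IP = −beta0/beta1, flat afterwards;
* oscillating M/W shapes: piecewise-linear through three inflection points,
  exactly zero at IP2, peak/trough v = beta0 + beta1 IP1 at IP1 and IP3,
  decaying to zero at the end of the interval.

Within a subject, Sigma_i = sigma^2 Omega(rho) with AR(1)
(rho^|j−j'|), compound-symmetry, or independent correlation; across
subjects Sigma = bdiag(Sigma_1, ..., Sigma_n). Microbiome realism comes from
two adaptations: left truncation at zero (per-block rejection sampling, with
censoring-to-zero fallback when the acceptance probability P(Y > 0) drops
below 0.1) and induced missingness (a chosen fraction of subjects gets a
chosen number of non-baseline observations replaced by 0 or NA; baselines
are never missing). Schedules are equidistant or asynchronous
(subject-specific uniform times with a fixed baseline), and an observed
study layout can be replicated k-fold to scale a pilot into a hypothetical
larger trial.

Estimators are scored with cosine similarity, Euclidean and normalized
Euclidean distance between estimated and true trend, and
sensitivity/specificity of any-timepoint detection across B repetitions;
`run_sweep()` crosses sigma × subjects-per-arm × q × trend form with a
pluggable detector.

## Worked example

```r
library(longdasim)

design <- sim_design(
  n_control = 20, n_treat = 20, control_mean = 2,
  covariance = cov_spec("compound", sigma = 1, rho = 0.7),
  trend = trend_spec("quadratic", beta = c(0, 3, -0.5)),
  num_timepoints = 7, t_interval = c(0, 6),
  missing_pct = 0.2, missing_per_subject = 2, miss_val = 0,
  seed = 42
)
sim <- simulate_feature(design)
sim
#> <sim_feature> N = 280 observations, 40 subjects
#>   sampling modes: rejection 40
#>   missing cells: 16
head(sim$records)
#>          Y ID time   group    Y_obs
#> 1 1.761263  1    0 Control 1.761263
#> 2 1.847047  1    1 Control 1.847047
#> 3 1.789936  1    2 Control 1.789936
#> 4 1.128639  1    3 Control 1.128639
#> 5 1.811289  1    4 Control 1.811289
#> 6 2.086209  1    5 Control 2.086209
head(sim$miss_data)
#>   miss_id miss_time
#> 1       3         3
#> 2       3         4
#> 3       6         4
#> 4       6         6
#> 5      16         3
#> 6      16         4
```

280 records are 40 subjects × 7 timepoints on [0, 6]; all 40 subject blocks
cleared the acceptance threshold, so the zero truncation used exact
rejection sampling. `round(0.2 × 40) = 8` subjects received 2 missing
non-baseline observations each (16 cells), imputed as 0 in `Y_obs` while
`Y` keeps the complete values.

A ten-feature community with four differentially abundant features, and a
small sweep scoring the bundled t-test detector:

```r
comm <- simulate_community(features = 10, diff_abun_features = 4,
                           design = design)
comm$abundance[1:4, 1:3]
#>           Sample_1 Sample_2 Sample_3
#> Diff_Bug1   1.2224   0.9440   0.5413
#> Diff_Bug2   2.9852   2.2386   1.8272
#> Diff_Bug3   2.1868   3.0078   3.5174
#> Diff_Bug4   1.9253   1.6434   1.8136

base <- sim_design(n_control = 10, n_treat = 10, control_mean = 2,
                   covariance = cov_spec("ar1", sigma = 1, rho = 0.7),
                   trend = trend_spec("L_up", beta = 1, ip = 3),
                   num_timepoints = 6, t_interval = c(0, 6))
cfg <- sweep_config(
  grids = list(sigma = c(1, 2)), repetitions = 10, base_design = base,
  trends = list(lup = trend_spec("L_up", beta = 1, ip = 3),
                null = trend_spec("none")),
  detector = "ttest", seed = 7
)
summarize_sweep(run_sweep(cfg), by = c("form", "sigma"))
#>   form sigma repetitions non_missing sensitivity specificity avg_cosine
#> 1  lup     1          10          10         1.0          NA  0.9603693
#> 2  lup     2          10          10         0.6          NA  0.8279535
#> 3 null     1          10          10          NA         0.9        NaN
#> 4 null     2          10          10          NA         1.0        NaN
```

Read: at sigma = 1 the simple per-timepoint t-test detects the hockey-stick
signal in all 10 repetitions (sensitivity 1.0) and its estimated trend
points almost exactly along the truth (mean cosine 0.96); doubling the noise
drops sensitivity to 0.6. On the null form it reports specificity
(0.9–1.0); direction-based metrics are undefined against a zero truth and
show as NaN.

A command-line wrapper with `simulate-feature`, `simulate-community`,
`sweep`, and `plot` subcommands is installed under `exec/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "longdasim", package = "longdasim"))')" \
  simulate-feature --config design.yaml --out-dir out --plot
```

Every run writes a JSON manifest (config snapshot, seed, package version,
sampling modes) sufficient to reproduce its outputs exactly.

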