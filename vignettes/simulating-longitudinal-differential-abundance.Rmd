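---
title: "Simulating longitudinal differential abundance: model and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating longitudinal differential abundance: model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longdasim)
```

## The model

Marker-gene and shotgun metagenomic abundances are non-normal counts, but
after the usual variance-stabilizing transformations (log, arcsinh) a single
feature's normalized abundance is approximately Gaussian. `longdasim`
therefore simulates one feature at a time from a multivariate normal

$$ Y \sim N(\mu, \Sigma), $$

where the $N = \sum_i q_i$ observations stack $n$ subjects with $q_i$
repeated measurements each. Subjects split into a control arm ($n_0$
subjects, IDs $1\ldots n_0$) and a treatment arm ($n_1$ subjects). The
control mean is constant over time, $\mu_0$; the treatment mean is
$\mu_0 + f(t)$, so the trend function $f$ *is* the differential abundance.
If $f(t_1) = 0$ the arms coincide at baseline. Multiple features are drawn
independently (a deliberate simplification, see *Limitations*).

The multivariate normal is the natural base distribution here because
longitudinal dependence enters directly through $\Sigma$, and the two
microbiome-specific complications — the non-negative domain and
missing/zero-inflated observations — can be layered on top (truncation and
missingness induction below).

## Trend families

`trend_spec()` supports:

* **Polynomial** (`linear`, `quadratic`, `cubic`):
  $f(t) = \beta_0 + \beta_1 t + \dots + \beta_p t^p$, $p \le 3$. All-zero
  coefficients give a null trend; `trend_spec("none")` is the explicit null.
* **Hockey sticks.** `L_up` is flat at zero before a single inflection point
  IP and increases linearly after it, $f(t) = \beta_1 (t - \mathrm{IP})
  \cdot 1[t \ge \mathrm{IP}]$ with $\beta_1 > 0$. `L_down` starts at
  $\beta_0 > 0$, decreases with slope $\beta_1 < 0$, and is flat at zero
  from the *implied* inflection point $\mathrm{IP} = -\beta_0/\beta_1$
  onward. Validation checks that the inflection point falls strictly inside
  the design's time interval.
* **Oscillating** (`oscillating_M`, `oscillating_W`): piecewise-linear
  spike-and-decay shapes through three ordered inflection points. The curve
  follows $\beta_0 + \beta_1 t$ up to $\mathrm{IP}_1$, where it attains
  $v = \beta_0 + \beta_1 \mathrm{IP}_1$; it is forced to exactly zero at
  $\mathrm{IP}_2$, returns to $v$ at $\mathrm{IP}_3$, and decays linearly
  back to zero at the end of the interval $t_q$. The sign of $\beta_1$
  selects the M (initial spike up) or W (initial dip down) orientation, and
  the two are exact sign mirrors of each other. Placing $\mathrm{IP}_2,
  \mathrm{IP}_3$ beyond $t_q$ yields absolute-value-type trends with a
  single interior kink; in that configuration the usual
  $\mathrm{IP}_3 \ne t_q$ restriction is moot.

A design choice worth recording: the oscillating family is *defined here by
its anchor points* — $(\mathrm{IP}_1, v)$, $(\mathrm{IP}_2, 0)$,
$(\mathrm{IP}_3, v)$, $(t_q, 0)$, linearly interpolated, with the
$\beta_0 + \beta_1 t$ ramp before $\mathrm{IP}_1$ — rather than by a single
printed formula. The anchors pin the curve unambiguously (zero at
$\mathrm{IP}_2$, peak value $v$ at $\mathrm{IP}_1$ and $\mathrm{IP}_3$,
return to zero at $t_q$), and the tests assert continuity and the mirror
symmetry directly. Segment membership uses left-closed/right-open intervals,
so evaluation at an inflection point is well defined and both adjoining
segments agree there; for `L_up`, both branches give $f(\mathrm{IP}) = 0$.

`evaluate_trend()` accepts arbitrary sorted timepoints, not just the design
grid, which is what makes asynchronous schedules and design-driven
simulation reuse one code path. Interval-dependent validation (inflection
points inside $(t_1, t_q)$) is enforced when an interval is supplied —
always the case inside a `sim_design` — but a bare spec can be probed at any
points.

## Covariance

Within a subject, $\Sigma_i = \sigma^2 \Omega(\rho)$ with a global standard
deviation $\sigma$ and one of three correlation structures: AR(1)
($\rho^{|j - j'|}$, indexed by measurement *order*), compound symmetry
(constant $\rho$), or independent. Between subjects, observations are
independent, so $\Sigma = \mathrm{bdiag}(\Sigma_1, \dots, \Sigma_n)$.
`block_covariance()` keeps $\Sigma$ as a list of per-subject blocks — the
dense $N \times N$ matrix is never formed for sampling, only assembled on
request via `as.matrix()` for inspection at small $N$.

Two parameter-range decisions:

* AR(1) accepts $\rho \in (-1, 1)$, where the block is always
  positive-definite.
* Compound symmetry is restricted to $\rho \in [0, 1)$. Negative
  exchangeable correlation is only positive-definite for
  $\rho > -1/(q-1)$, a block-size-dependent bound that is rarely what a
  user intends; rejecting negatives with a clear message is safer than a
  silently $q$-dependent domain.
* For asynchronous schedules the AR(1) exponent still counts measurement
  order, not elapsed time. A continuous-time (distance-based) kernel is a
  non-goal.

## Truncation: the rejection/censoring hybrid

Transformed abundances are non-negative, so by default draws come from the
left-truncated distribution $TN(\mu, \Sigma, a\mathbf{1})$ with $a = 0$
(`truncation_spec(enabled = FALSE)` turns this off). Sampling works per
subject block through the Cholesky factor of $\Sigma_i$:

1. Estimate the block acceptance probability
   $p_{\mathrm{acpt}} = P(Y_i > a\mathbf{1})$ by a Monte Carlo pilot
   (default 1000 unconstrained draws). The pilot is dimension-robust and
   dependency-free; its error is the usual binomial Monte Carlo error,
   which is immaterial because $p_{\mathrm{acpt}}$ only gates a mode
   switch.
2. If $p_{\mathrm{acpt}}$ exceeds the threshold (default 0.1), draw the
   whole block repeatedly until every coordinate exceeds $a$ (rejection
   sampling — exact truncated-normal draws). A hard cap of $10^5$ redraws
   per block turns a misconfigured design into a loud error rather than a
   silent stall.
3. Otherwise rejection would be impractically slow; the block is drawn once
   and coordinates below $a$ are censored to $a$ (point imputation). This
   reproduces the characteristic point mass at zero: for a univariate block
   the zero mass is $\Phi((a - \mu)/\sigma)$, which the test suite checks
   against the normal CDF.

Because blocks are independent, the acceptance rule operates per distinct
(mean block, covariance block) pair — in a standard two-arm design that is
once per arm, so each arm is sampled in a single coherent mode. The two
modes agree in distribution as $p_{\mathrm{acpt}} \to 1$ (asserted by a
KS test at $\mu = 5\sigma$). The per-block modes used are returned with
the dataset and recorded in CLI manifests.

## Sampling schedules and missingness

Equidistant mode gives every subject the same $q$ evenly spaced points on
$[t_1, t_q]$ inclusive. Asynchronous mode fixes each subject's baseline at
$t_1$ — every subject is assumed to have a baseline measurement — and draws
the remaining $q - 1$ times i.i.d. uniform on the open interval
$(t_1, t_q)$, sorted within subject. The open interval avoids manufacturing
ties with the interval endpoints; with continuous uniforms, interior ties
have probability zero.

Missingness emulates features that are present but undetected (impute 0) or
samples not collected (impute `NA`): `round(missing_pct * n)` subjects are
chosen without replacement (base R `round`, nearest with ties to even — the
rounding rule only matters at exact halves), and for each chosen subject
`missing_per_subject` of its non-baseline times are drawn without
replacement and overwritten in `Y_obs`. The complete outcome `Y` is kept
alongside, and `miss_data` lists every induced cell, so tests can verify
`Y` and `Y_obs` disagree on exactly those cells.

## Communities and design-driven simulation

`simulate_community()` draws multiple features over one shared schedule:
the first `diff_abun_features` carry the design's trend, the rest are null.
One master seed derives per-feature substreams (`sample.int` of the full
integer range), so the community is reproducible as a whole and any single
feature can be re-drawn in isolation. All differential features share one
trend spec — per-feature trend heterogeneity is a straightforward extension
but not implemented, matching the single-trend community interface.

`simulate_from_design()` drives the same pipeline from an observed layout
(a table of IDs, times, groups): each original subject's time vector is
replicated `replication_factor` times as new subjects with the group label
preserved, which is how a 12-subject pilot becomes a hypothetical 60-subject
trial that keeps the pilot's exact, possibly irregular, collection schedule.
Blocks may then have unequal $q_i$; the block representation handles this
without special cases.

## Scoring estimators

Given an estimated trend $\hat f$ and the truth $f$ on a common grid, the
package computes cosine similarity
$\hat f^\top f / (\|\hat f\|\|f\|) \in [-1, 1]$, Euclidean distance
$\|\hat f - f\| \in [0, \infty)$, and normalized Euclidean distance
$\|\hat f/\|\hat f\| - f/\|f\|\| \in [0, 2]$, which satisfies
$d_{\mathrm{norm}}^2 = 2(1 - \cos)$ and, unlike the raw distance, is
comparable across grids of different length. When the true trend is
identically zero the direction-based metrics are undefined; the functions
raise an error rather than return a convention, and the sweep harness
records `NA` for those cells (null-form cells are scored by specificity
instead). Detection is summarized over $B$ repetitions as sensitivity (any
differential abundance detected, among truly differential repetitions) and
specificity (none detected, among truly null ones); repetitions where the
estimator returned no result are excluded from denominators and reported as
the `non_missing` count.

`run_sweep()` crosses grids over $\sigma$, subjects per arm, $q$, and
$\rho$ with a set of trend forms, simulates $B$ repetitions per cell from
deterministic seed substreams (a matrix of substream seeds drawn up front,
so results are independent of execution order and reproducible), and scores
a pluggable detector. Two reference detectors ship: a perfect oracle, whose
only legitimate use is the harness self-test (sensitivity and specificity
must both be exactly 1), and a per-timepoint Welch t-test with
Bonferroni-corrected any-timepoint detection — a deliberately simple,
honest baseline. The smoothing-spline ANOVA estimator that motivated the
metrics is an external method and is intentionally not reimplemented;
published benchmark numbers for it depend on that estimator and are out of
scope for this package, whose claims are about the simulator and harness.

## Numerical and degenerate-input choices

* Draws use the upper Cholesky factor per block; a non-positive-definite
  block fails with an explicit factorization error naming the likely cause.
* TSV output writes doubles with 17 significant digits so a write/read
  round trip is exact, and `NA` is the not-available marker.
* Metric functions reject length mismatches, `NA`s, and zero-norm inputs
  instead of propagating `NaN`.
* `sim_design()` validates everything at construction (group sizes, $q \ge
  2$, interval orientation, missingness bounds including the
  baseline-never-missing rule, trend-vs-interval compatibility), so
  downstream code can assume a coherent design.

## What the generator does and does not emulate

The generator reproduces the features of longitudinal marker-gene data that
matter for benchmarking trend estimators: non-negativity with a point mass
at zero, within-subject correlation, small numbers of subjects and repeated
measurements, irregular collection times, and missing observations. It does
**not** model sequencing depth, compositionality, or integer counts — the
scale is the transformed (approximately Gaussian) one — nor between-feature
dependence or ecological dynamics. Passing tests therefore demonstrate
correctness of the simulator's own contracts and of estimator plumbing, not
that any estimator will perform identically on real count data.

Problem sizes in the test suite and acceptance script were chosen to keep
Monte Carlo error well inside the asserted 3-standard-error bands while
running comfortably on a laptop: moment-recovery checks use 500 subjects
per arm at $q = 6$; truncation point-mass and KS checks use $8\,000$ to
$10\,000$ univariate blocks; the harness self-test uses $B = 20$
repetitions across nine trend forms; the factorial-grid bookkeeping is
checked at $B = 2$ (54 runs) together with the exact $\times 50$
extrapolation to the full $27 \times 100 = 2\,700$-repetition schedule.

## A worked example

```{r example}
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
head(sim$records)
head(sim$miss_data)
```

```{r community}
comm <- simulate_community(features = 10, diff_abun_features = 4,
                           design = design)
comm
comm$abundance[1:4, 1:3]
```

```{r sweep}
base <- sim_design(n_control = 10, n_treat = 10, control_mean = 2,
                   covariance = cov_spec("ar1", sigma = 1, rho = 0.7),
                   trend = trend_spec("L_up", beta = 1, ip = 3),
                   num_timepoints = 6, t_interval = c(0, 6))
cfg <- sweep_config(
  grids = list(sigma = c(1, 2)),
  repetitions = 10,
  base_design = base,
  trends = list(lup = trend_spec("L_up", beta = 1, ip = 3),
                null = trend_spec("none")),
  detector = "ttest", seed = 7
)
summarize_sweep(run_sweep(cfg), by = c("form", "sigma"))
```
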