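#' Parameterize one simulated longitudinal feature
#'
#' Bundles everything needed to simulate a single feature: group sizes, the
#' constant control mean, the within-subject covariance, the treatment trend
#' `f(t)`, the sampling schedule, missingness settings, truncation, and the
#' RNG seed. The model is `Y ~ N(mu, Sigma)` (optionally left-truncated) with
#' control-group mean `mu0` at every time and treatment-group mean
#' `mu0 + f(t)`.
#'
#' @param n_control,n_treat Subjects per arm (`>= 1`). Control subjects get
#'   IDs `1..n_control`, treatment the remaining ones.
#' @param control_mean Constant control-group mean `mu0` (abundance units).
#' @param covariance A [cov_spec()].
#' @param trend A [trend_spec()] for the treatment arm; `trend_spec("none")`
#'   simulates no differential abundance.
#' @param num_timepoints Repeated measurements per subject `q >= 2`.
#' @param t_interval Numeric pair `(t1, tq)`, `t1 < tq` (time units).
#' @param asynch_time If `TRUE`, each subject keeps the baseline at `t1` and
#'   draws the remaining `q - 1` times uniformly on `(t1, tq)` (sorted);
#'   otherwise all subjects share the `q` equidistant points.
#' @param missing_pct Fraction of subjects, in `[0, 1]`, selected (without
#'   replacement) to receive missing values.
#' @param missing_per_subject Number of non-baseline measurements per selected
#'   subject set to missing; at most `q - 1` (the baseline is never missing).
#' @param miss_val Value imputed at missing cells: a number (typically `0`,
#'   a feature present but undetected) or `NA` (a sample not collected).
#' @param truncation A [truncation_spec()].
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `sim_design`.
#' @examples
#' sim_design(n_control = 20, n_treat = 20, control_mean = 2,
#'            covariance = cov_spec("compound", sigma = 1, rho = 0.7),
#'            trend = trend_spec("quadratic", beta = c(0, 3, -0.5)),
#'            num_timepoints = 7, t_interval = c(0, 6))
#' @export
sim_design <- function(n_control, n_treat, control_mean,
                       covariance = cov_spec(),
                       trend = trend_spec("none"),
                       num_timepoints, t_interval,
                       asynch_time = FALSE,
                       missing_pct = 0, missing_per_subject = 0L,
                       miss_val = NA_real_,
                       truncation = truncation_spec(),
                       seed = NULL) {
  n_control <- as.integer(n_control)
  n_treat <- as.integer(n_treat)
  num_timepoints <- as.integer(num_timepoints)
  missing_per_subject <- as.integer(missing_per_subject)
  stopifnot(inherits(covariance, "cov_spec"),
            inherits(trend, "trend_spec"),
            inherits(truncation, "trunc_spec"),
            is.numeric(control_mean), length(control_mean) == 1L)
  if (n_control < 1L || n_treat < 1L) {
    stop("both arms need at least one subject", call. = FALSE)
  }
  if (num_timepoints < 2L) stop("num_timepoints must be >= 2", call. = FALSE)
  if (length(t_interval) != 2L || t_interval[1L] >= t_interval[2L]) {
    stop("t_interval must be (t1, tq) with t1 < tq", call. = FALSE)
  }
  if (missing_pct < 0 || missing_pct > 1) {
    stop("missing_pct must lie in [0, 1]", call. = FALSE)
  }
  if (missing_per_subject < 0L || missing_per_subject > num_timepoints - 1L) {
    stop("missing_per_subject must lie in [0, q - 1]; the baseline ",
         "measurement is never missing", call. = FALSE)
  }
  if (!(length(miss_val) == 1L && (is.na(miss_val) || is.numeric(miss_val)))) {
    stop("miss_val must be a single number or NA", call. = FALSE)
  }
  viol <- validate_trend(trend, t_interval)
  if (length(viol) > 0L) {
    stop("trend incompatible with t_interval: ",
         paste(viol, collapse = "; "), call. = FALSE)
  }
  structure(list(n_control = n_control, n_treat = n_treat,
                 control_mean = control_mean, covariance = covariance,
                 trend = trend, num_timepoints = num_timepoints,
                 t_interval = as.numeric(t_interval),
                 asynch_time = isTRUE(asynch_time),
                 missing_pct = missing_pct,
                 missing_per_subject = missing_per_subject,
                 miss_val = as.numeric(miss_val),
                 truncation = truncation,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design>", x$n_control, "control +", x$n_treat, "treatment,",
      x$num_timepoints, "timepoints on [", x$t_interval[1L], ",",
      x$t_interval[2L], "]\n")
  cat("  control mean:", x$control_mean, "; trend:", x$trend$form,
      "; covariance:", x$covariance$structure, "\n")
  invisible(x)
}

#' Per-subject sampling schedules
#'
#' Equidistant mode: every subject shares the `q` evenly spaced points from
#' `t1` to `tq` inclusive. Asynchronous mode: each subject keeps the baseline
#' at `t1` and draws the remaining `q - 1` times i.i.d. uniform on the open
#' interval `(t1, tq)`, returned sorted ascending.
#'
#' @param design A [sim_design()].
#' @return List of per-subject numeric time vectors (length `n0 + n1`).
#' @export
make_timepoints <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  n <- design$n_control + design$n_treat
  q <- design$num_timepoints
  t1 <- design$t_interval[1L]
  tq <- design$t_interval[2L]
  if (!design$asynch_time) {
    grid <- seq(t1, tq, length.out = q)
    return(rep(list(grid), n))
  }
  lapply(seq_len(n), function(i) {
    c(t1, sort(stats::runif(q - 1L, min = t1, max = tq)))
  })
}

#' Mean vector of the full design
#'
#' Control entries are all `mu0`; the treatment entry of subject `i` at time
#' `t` is `mu0 + f(t)`, evaluated at that subject's own times (so
#' asynchronous schedules are handled transparently).
#'
#' @param design A [sim_design()].
#' @param times Per-subject time vectors from [make_timepoints()].
#' @return List with `mu` (the concatenated N-vector) and `blocks` (the
#'   per-subject mean vectors, in subject order).
#' @export
build_mean_vector <- function(design, times) {
  stopifnot(inherits(design, "sim_design"), is.list(times))
  n <- design$n_control + design$n_treat
  if (length(times) != n) {
    stop("times must hold one vector per subject", call. = FALSE)
  }
  mu0 <- design$control_mean
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    if (i <= design$n_control) {
      blocks[[i]] <- rep(mu0, length(times[[i]]))
    } else {
      blocks[[i]] <- mu0 + evaluate_trend(design$trend, times[[i]],
                                          t_interval = design$t_interval)
    }
  }
  list(mu = unlist(blocks, use.names = FALSE), blocks = blocks)
}

empty_miss_data <- function() {
  data.frame(miss_id = integer(), miss_time = numeric())
}

#' Induce missing observations
#'
#' Selects `round(missing_pct * n)` subjects without replacement; for each,
#' draws `missing_per_subject` of that subject's non-baseline times without
#' replacement and replaces `Y_obs` there with `miss_val`. The complete
#' outcome `Y` is untouched and the baseline (each subject's first
#' measurement) can never be missing.
#'
#' @param dataset A `sim_feature` result (see [simulate_feature()]).
#' @param design The [sim_design()] that produced it (source of
#'   `missing_pct`, `missing_per_subject`, `miss_val`).
#' @return The dataset with updated `records$Y_obs` and `miss_data` listing
#'   every `(miss_id, miss_time)` pair.
#' @export
induce_missingness <- function(dataset, design) {
  stopifnot(inherits(dataset, "sim_feature"), inherits(design, "sim_design"))
  rec <- dataset$records
  ids <- unique(rec$ID)
  n <- length(ids)
  n_sel <- round(design$missing_pct * n)
  if (n_sel == 0L || design$missing_per_subject == 0L) {
    dataset$miss_data <- empty_miss_data()
    return(dataset)
  }
  qs <- table(rec$ID)
  if (design$missing_per_subject > min(qs) - 1L) {
    stop("missing_per_subject exceeds q - 1 for at least one subject",
         call. = FALSE)
  }
  sel <- sort(sample(ids, n_sel, replace = FALSE))
  miss <- lapply(sel, function(id) {
    ti <- rec$time[rec$ID == id]
    candidates <- sort(ti)[-1L]  # baseline excluded
    picked <- candidates[sample.int(length(candidates),
                                    design$missing_per_subject)]
    data.frame(miss_id = id, miss_time = sort(picked))
  })
  miss <- do.call(rbind, miss)
  for (k in seq_len(nrow(miss))) {
    hit <- rec$ID == miss$miss_id[k] & rec$time == miss$miss_time[k]
    rec$Y_obs[hit] <- design$miss_val
  }
  dataset$records <- rec
  dataset$miss_data <- miss
  dataset
}

# Core pipeline once per-subject times and groups are fixed. `groups` is a
# character vector ("Control"/"Treatment") aligned with `times`.
simulate_at_times <- function(design, times, groups = NULL) {
  n <- length(times)
  if (is.null(groups)) {
    groups <- rep(c("Control", "Treatment"),
                  c(design$n_control, design$n_treat))
  }
  mu <- build_mean_vector_groups(design, times, groups)
  sigma <- block_covariance(design$covariance, lengths(times))
  draw <- sample_truncated_mvn(mu$blocks, unclass(sigma),
                               trunc = design$truncation)
  records <- data.frame(
    Y = draw$y,
    ID = rep(seq_len(n), lengths(times)),
    time = unlist(times, use.names = FALSE),
    group = rep(groups, lengths(times)),
    Y_obs = draw$y,
    stringsAsFactors = FALSE
  )
  out <- structure(list(records = records,
                        mu = mu$mu,
                        sigma = sigma,
                        n_total = nrow(records),
                        miss_data = empty_miss_data(),
                        modes = draw$modes),
                   class = "sim_feature")
  induce_missingness(out, design)
}

# Mean builder for explicit group labels (simulate_from_design may interleave
# arms); control entries mu0, treatment entries mu0 + f(t).
build_mean_vector_groups <- function(design, times, groups) {
  blocks <- vector("list", length(times))
  for (i in seq_along(times)) {
    if (groups[i] == "Control") {
      blocks[[i]] <- rep(design$control_mean, length(times[[i]]))
    } else {
      blocks[[i]] <- design$control_mean +
        evaluate_trend(design$trend, times[[i]],
                       t_interval = design$t_interval)
    }
  }
  list(mu = unlist(blocks, use.names = FALSE), blocks = blocks)
}

#' Simulate one longitudinal feature
#'
#' Runs the full pipeline for a single feature: sampling schedule, mean
#' vector, block covariance, (truncated) multivariate normal draw, and
#' missingness induction.
#'
#' @param design A [sim_design()].
#' @return An object of class `sim_feature`: a list with
#'   * `records`: long-format data frame with columns `Y` (complete outcome),
#'     `ID` (subject, control IDs first), `time`, `group`, `Y_obs` (outcome
#'     after missingness), sorted by ID then time;
#'   * `mu`: the N-vector of means;
#'   * `sigma`: the block covariance ([block_covariance()] object);
#'   * `n_total`: `N = sum(q_i)`;
#'   * `miss_data`: data frame of induced `(miss_id, miss_time)` pairs;
#'   * `modes`: per-subject sampling mode used.
#' @examples
#' d <- sim_design(n_control = 5, n_treat = 5, control_mean = 2,
#'                 covariance = cov_spec("ar1", sigma = 1, rho = 0.5),
#'                 trend = trend_spec("linear", beta = c(0, 0.5)),
#'                 num_timepoints = 4, t_interval = c(0, 6), seed = 42)
#' sim <- simulate_feature(d)
#' head(sim$records)
#' @export
simulate_feature <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  times <- make_timepoints(design)
  simulate_at_times(design, times)
}

#' @export
print.sim_feature <- function(x, ...) {
  cat("<sim_feature> N =", x$n_total, "observations,",
      length(unique(x$records$ID)), "subjects\n")
  cat("  sampling modes:",
      paste(names(table(x$modes)), table(x$modes), collapse = ", "), "\n")
  cat("  missing cells:", nrow(x$miss_data), "\n")
  invisible(x)
}

#' Simulate a multi-feature community table
#'
#' Draws `features` independent features over one shared sample schedule:
#' `diff_abun_features` of them carry the design's treatment trend
#' (rows `Diff_Bug1, Diff_Bug2, ...`), the remainder have no differential
#' abundance (rows `NoDiffBug_1, ...`). Each feature gets its own
#' deterministic RNG substream derived from the design seed, so features are
#' independent yet individually reproducible. Missingness is induced per
#' feature.
#'
#' @param features Total number of features (`>= 1`).
#' @param diff_abun_features Number of differentially abundant features,
#'   between 0 and `features`.
#' @param design A [sim_design()].
#' @return An object of class `sim_community`: a list with `abundance`
#'   (features x N matrix of `Y_obs`, columns `Sample_1..Sample_N` ordered by
#'   ID then time) and `sample_meta` (data frame `ID`, `time`, `group`,
#'   `Sample_ID`).
#' @examples
#' d <- sim_design(n_control = 4, n_treat = 4, control_mean = 2,
#'                 covariance = cov_spec("compound", sigma = 1, rho = 0.7),
#'                 trend = trend_spec("L_down", beta = c(2, -0.5)),
#'                 num_timepoints = 5, t_interval = c(0, 10), seed = 7)
#' comm <- simulate_community(features = 6, diff_abun_features = 2, design = d)
#' dim(comm$abundance)
#' @export
simulate_community <- function(features, diff_abun_features, design) {
  stopifnot(inherits(design, "sim_design"))
  features <- as.integer(features)
  diff_abun_features <- as.integer(diff_abun_features)
  if (features < 1L) stop("features must be >= 1", call. = FALSE)
  if (diff_abun_features < 0L || diff_abun_features > features) {
    stop("diff_abun_features must lie in [0, features]", call. = FALSE)
  }
  if (!is.null(design$seed)) set.seed(design$seed)
  times <- make_timepoints(design)  # one schedule shared by all features
  feature_seeds <- sample.int(.Machine$integer.max, features)

  null_design <- design
  null_design$trend <- trend_spec("none")

  draw_one <- function(k) {
    set.seed(feature_seeds[k])
    d <- if (k <= diff_abun_features) design else null_design
    simulate_at_times(d, times)
  }
  sims <- lapply(seq_len(features), draw_one)

  meta <- sims[[1L]]$records[, c("ID", "time", "group")]
  meta$Sample_ID <- paste0("Sample_", seq_len(nrow(meta)))
  rownames(meta) <- meta$Sample_ID

  abundance <- do.call(rbind, lapply(sims, function(s) s$records$Y_obs))
  rownames(abundance) <- c(
    if (diff_abun_features > 0L) paste0("Diff_Bug", seq_len(diff_abun_features)),
    if (features > diff_abun_features)
      paste0("NoDiffBug_", seq_len(features - diff_abun_features))
  )
  colnames(abundance) <- meta$Sample_ID

  structure(list(abundance = abundance, sample_meta = meta),
            class = "sim_community")
}

#' @export
print.sim_community <- function(x, ...) {
  cat("<sim_community>", nrow(x$abundance), "features x",
      ncol(x$abundance), "samples\n")
  invisible(x)
}

#' Simulate from an observed sample design with subject replication
#'
#' Drives the simulator from a real study's layout: a table of subject IDs,
#' measurement times, and group labels. Each original subject's time vector is
#' copied `replication_factor` times as new subjects (group preserved, fresh
#' IDs with all control subjects numbered first), then the standard
#' mean/covariance/sampling pipeline runs on the possibly unequal-`q_i`
#' design. This is how a small pilot study is scaled up to a hypothetical
#' larger trial while keeping its exact (asynchronous) collection schedule.
#'
#' @param sample_design Data frame with columns `ID`, `time`, `group`
#'   (`"Control"`/`"Treatment"`); times sorted within subject, every subject
#'   with at least one time.
#' @param replication_factor Copies of each original subject (`>= 1`).
#' @param control_mean Constant control-group mean.
#' @param covariance A [cov_spec()].
#' @param trend A [trend_spec()].
#' @param truncation A [truncation_spec()].
#' @param seed Integer RNG seed or `NULL`.
#' @return A `sim_feature` object (no missingness is induced).
#' @export
simulate_from_design <- function(sample_design, replication_factor = 1L,
                                 control_mean, covariance, trend,
                                 truncation = truncation_spec(),
                                 seed = NULL) {
  replication_factor <- as.integer(replication_factor)
  if (replication_factor < 1L) {
    stop("replication_factor must be >= 1", call. = FALSE)
  }
  req <- c("ID", "time", "group")
  if (!is.data.frame(sample_design) || !all(req %in% names(sample_design)) ||
      nrow(sample_design) == 0L) {
    stop("sample_design must be a non-empty data frame with columns ",
         "ID, time, group", call. = FALSE)
  }
  if (!all(sample_design$group %in% c("Control", "Treatment"))) {
    stop("group must be 'Control' or 'Treatment'", call. = FALSE)
  }
  ids <- unique(sample_design$ID)
  subj_times <- lapply(ids, function(id) {
    ti <- sample_design$time[sample_design$ID == id]
    if (is.unsorted(ti)) stop("times must be sorted within subject ", id,
                              call. = FALSE)
    ti
  })
  subj_group <- vapply(ids, function(id) {
    g <- unique(sample_design$group[sample_design$ID == id])
    if (length(g) != 1L) stop("subject ", id, " has conflicting group labels",
                              call. = FALSE)
    g
  }, character(1))

  # replicate, then renumber with control subjects first
  rep_idx <- rep(seq_along(ids), each = replication_factor)
  times <- subj_times[rep_idx]
  groups <- subj_group[rep_idx]
  ord <- order(groups != "Control")  # stable: controls first
  times <- times[ord]
  groups <- groups[ord]

  t_interval <- range(unlist(subj_times))
  qs <- lengths(times)
  design <- sim_design(
    n_control = max(1L, sum(groups == "Control")),
    n_treat = max(1L, sum(groups == "Treatment")),
    control_mean = control_mean, covariance = covariance, trend = trend,
    num_timepoints = max(2L, min(qs)), t_interval = t_interval,
    truncation = truncation, seed = seed
  )
  if (!is.null(seed)) set.seed(as.integer(seed))
  simulate_at_times(design, times, groups = groups)
}
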