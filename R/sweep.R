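#' Configure a factorial parameter sweep
#'
#' Describes a grid of simulation settings crossed with one or more trend
#' forms, each simulated `repetitions` times and scored by a detector. Grid
#' parameters override the corresponding fields of `base_design`; recognised
#' names are `sigma`, `n_per_group` (sets both arms), `q` (number of
#' timepoints), and `rho`.
#'
#' @param grids Named list of numeric value vectors, e.g.
#'   `list(sigma = c(1, 2, 4), n_per_group = c(10, 20, 50), q = c(3, 6, 12))`.
#' @param repetitions Number of repetitions `B >= 1` per grid cell and form.
#' @param base_design A [sim_design()] template supplying all parameters not
#'   in the grid.
#' @param trends Named list of [trend_spec()] objects to sweep over; defaults
#'   to the base design's trend under the name of its form.
#' @param detector Detector name (`"oracle"`, `"ttest"`) or a detector
#'   function; see [detectors].
#' @param seed Integer master seed; every repetition gets a deterministic
#'   substream, so results are reproducible and independent of execution
#'   order.
#' @return An object of class `sweep_config`.
#' @seealso [run_sweep()], [summarize_sweep()]
#' @export
sweep_config <- function(grids, repetitions, base_design,
                         trends = NULL, detector = "oracle", seed = 1L) {
  stopifnot(inherits(base_design, "sim_design"))
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) stop("repetitions must be >= 1", call. = FALSE)
  if (!is.list(grids) || length(grids) == 0L || is.null(names(grids)) ||
      any(names(grids) == "") || any(lengths(grids) == 0L)) {
    stop("grids must be a non-empty named list of value vectors",
         call. = FALSE)
  }
  allowed <- c("sigma", "n_per_group", "q", "rho")
  bad <- setdiff(names(grids), allowed)
  if (length(bad) > 0L) {
    stop("unknown grid parameter(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  if (is.null(trends)) {
    trends <- stats::setNames(list(base_design$trend), base_design$trend$form)
  }
  if (!all(vapply(trends, inherits, logical(1), "trend_spec")) ||
      is.null(names(trends))) {
    stop("trends must be a named list of trend_spec objects", call. = FALSE)
  }
  structure(list(grids = grids, repetitions = repetitions,
                 base_design = base_design, trends = trends,
                 detector = detector, seed = as.integer(seed)),
            class = "sweep_config")
}

#' Number of repetitions a sweep schedules
#'
#' `B * prod(grid sizes) * number of trend forms`, before any estimator
#' failures (which are flagged in the results, not dropped).
#'
#' @param config A [sweep_config()].
#' @return Integer count.
#' @export
scheduled_repetitions <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  config$repetitions * prod(lengths(config$grids)) * length(config$trends)
}

apply_setting <- function(base_design, setting, trend, seed) {
  d <- base_design
  if (!is.null(setting$sigma)) d$covariance$sigma <- setting$sigma
  if (!is.null(setting$rho)) d$covariance$rho <- setting$rho
  if (!is.null(setting$n_per_group)) {
    d$n_control <- as.integer(setting$n_per_group)
    d$n_treat <- as.integer(setting$n_per_group)
  }
  if (!is.null(setting$q)) d$num_timepoints <- as.integer(setting$q)
  d$trend <- trend
  d$seed <- seed
  # re-validate the modified design through the constructor
  sim_design(n_control = d$n_control, n_treat = d$n_treat,
             control_mean = d$control_mean, covariance = d$covariance,
             trend = d$trend, num_timepoints = d$num_timepoints,
             t_interval = d$t_interval, asynch_time = d$asynch_time,
             missing_pct = d$missing_pct,
             missing_per_subject = min(d$missing_per_subject,
                                       d$num_timepoints - 1L),
             miss_val = d$miss_val, truncation = d$truncation, seed = d$seed)
}

#' Run a parameter sweep
#'
#' For every grid cell and trend form, simulates `B` datasets (each from its
#' own deterministic seed substream), runs the detector on each, and computes
#' the trend-recovery metrics against the true trend at the design grid.
#' Detector exceptions are caught and recorded via the `estimate_missing`
#' flag. Row count equals [scheduled_repetitions()].
#'
#' @param config A [sweep_config()].
#' @return A tidy data frame with one row per repetition: the grid columns,
#'   `form`, `rep`, `truth_is_diff`, `detected`, `estimate_missing`,
#'   `cosine`, `euclidean`, `norm_euclidean` (trend-recovery metrics are `NA`
#'   when no estimate was produced or when the true trend is null, where
#'   direction-based metrics are undefined).
#' @examples
#' base <- sim_design(n_control = 5, n_treat = 5, control_mean = 2,
#'                    covariance = cov_spec("ar1", sigma = 1, rho = 0.7),
#'                    trend = trend_spec("L_up", beta = 1, ip = 3),
#'                    num_timepoints = 6, t_interval = c(0, 6))
#' cfg <- sweep_config(grids = list(sigma = c(1, 2)), repetitions = 2,
#'                     base_design = base, detector = "oracle", seed = 9)
#' run_sweep(cfg)
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  detector <- get_detector(config$detector)
  settings <- expand.grid(c(config$grids,
                            list(form = names(config$trends))),
                          stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
  n_settings <- nrow(settings)
  B <- config$repetitions
  set.seed(config$seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max, n_settings * B),
                     nrow = n_settings, ncol = B)

  rows <- vector("list", n_settings * B)
  k <- 0L
  for (s in seq_len(n_settings)) {
    setting <- as.list(settings[s, , drop = FALSE])
    trend <- config$trends[[setting$form]]
    for (b in seq_len(B)) {
      design <- apply_setting(config$base_design, setting, trend,
                              seed_mat[s, b])
      grid <- seq(design$t_interval[1L], design$t_interval[2L],
                  length.out = design$num_timepoints)
      f_true <- evaluate_trend(trend, grid, t_interval = design$t_interval)
      truth_is_diff <- any(f_true != 0)
      dataset <- simulate_feature(design)
      truth <- list(grid = grid, f_true = f_true,
                    truth_is_diff = truth_is_diff)
      res <- tryCatch(detector(dataset, truth), error = function(e) NULL)
      missing_est <- is.null(res) || is.na(res$detected)
      f_hat <- if (!missing_est) res$f_hat else NULL
      cosine <- euclid <- norm_euclid <- NA_real_
      if (!is.null(f_hat) && !anyNA(f_hat)) {
        euclid <- euclidean_distance(f_hat, f_true)
        if (truth_is_diff && any(f_hat != 0)) {
          cosine <- cosine_similarity(f_hat, f_true)
          norm_euclid <- normalized_euclidean(f_hat, f_true)
        }
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        setting, rep = b, truth_is_diff = truth_is_diff,
        detected = if (missing_est) NA else isTRUE(res$detected),
        estimate_missing = missing_est,
        cosine = cosine, euclidean = euclid, norm_euclidean = norm_euclid,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate sweep results
#'
#' Group-wise summary of a [run_sweep()] result: repetition counts, the
#' number of repetitions with a usable estimate, sensitivity (for
#' differential forms) or specificity (for null forms) over those, and the
#' means of the continuous trend-recovery metrics.
#'
#' @param results Data frame from [run_sweep()].
#' @param by Character vector of grouping columns (default `"form"`; add grid
#'   columns like `c("form", "sigma", "n_per_group", "q")` for a per-setting
#'   table).
#' @return A data frame with columns `by...`, `repetitions`, `non_missing`,
#'   `sensitivity`, `specificity`, `avg_cosine`, `avg_euclidean`,
#'   `avg_norm_euclidean`.
#' @export
summarize_sweep <- function(results, by = "form") {
  stopifnot(is.data.frame(results), nrow(results) > 0L,
            all(by %in% names(results)))
  key <- interaction(results[by], drop = TRUE, lex.order = TRUE)
  groups <- split(results, key)
  out <- lapply(groups, function(g) {
    ok <- !g$estimate_missing
    truth_diff <- all(g$truth_is_diff)
    sens <- spec <- NA_real_
    if (any(ok)) {
      if (truth_diff) {
        sens <- sensitivity(g$detected[ok], g$truth_is_diff[ok])$estimate
      } else if (!any(g$truth_is_diff)) {
        spec <- specificity(g$detected[ok], g$truth_is_diff[ok])$estimate
      }
    }
    cbind(
      g[1L, by, drop = FALSE],
      data.frame(
        repetitions = nrow(g),
        non_missing = sum(ok),
        sensitivity = sens,
        specificity = spec,
        avg_cosine = mean(g$cosine[ok], na.rm = TRUE),
        avg_euclidean = mean(g$euclidean[ok], na.rm = TRUE),
        avg_norm_euclidean = mean(g$norm_euclidean[ok], na.rm = TRUE)
      )
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
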