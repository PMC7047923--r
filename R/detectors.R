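#' Reference detectors for the sweep harness
#'
#' A detector is any function `function(dataset, truth)` taking a
#' `sim_feature` dataset and a `truth` list (fields `grid`, the design
#' timepoint grid; `f_true`, the true trend at the grid; and
#' `truth_is_diff`), and returning a list with `detected` (single logical:
#' any differential abundance reported at any timepoint) and `f_hat` (the
#' estimated trend at the grid, or `NULL` when the method yields no
#' estimate). Exceptions and `NULL` estimates are recorded as missing
#' estimates by [run_sweep()], never dropped silently.
#'
#' Two reference detectors ship with the package:
#'
#' * `detector_oracle()`: returns the truth exactly — detects iff the true
#'   trend is non-null and reports `f_hat = f_true`. Useful only as the
#'   harness self-test (it must score sensitivity and specificity 1).
#' * `detector_ttest()`: per-timepoint two-sample Welch t-tests on `Y_obs`
#'   (missing markers excluded) with Bonferroni-corrected any-timepoint
#'   detection at level `alpha`; `f_hat` is the per-timepoint difference of
#'   group means. Requires a shared (equidistant) schedule with at least two
#'   observations per group and timepoint.
#'
#' The headline smoothing-spline ANOVA estimator evaluated in the literature
#' is deliberately not bundled: the harness accepts any detector matching
#' this interface, so external estimators plug in without changes here.
#'
#' @param alpha Familywise error level for `detector_ttest` (Bonferroni over
#'   the `q` timepoints).
#' @return A detector function.
#' @examples
#' det <- detector_oracle()
#' @name detectors
NULL

#' @rdname detectors
#' @export
detector_oracle <- function() {
  function(dataset, truth) {
    list(detected = any(truth$f_true != 0),
         f_hat = if (any(truth$f_true != 0)) truth$f_true else NULL)
  }
}

#' @rdname detectors
#' @export
detector_ttest <- function(alpha = 0.05) {
  force(alpha)
  function(dataset, truth) {
    rec <- dataset$records
    rec <- rec[!is.na(rec$Y_obs), , drop = FALSE]
    grid <- truth$grid
    q <- length(grid)
    pvals <- numeric(q)
    f_hat <- numeric(q)
    for (j in seq_len(q)) {
      at <- rec[rec$time == grid[j], , drop = FALSE]
      y0 <- at$Y_obs[at$group == "Control"]
      y1 <- at$Y_obs[at$group == "Treatment"]
      if (length(y0) < 2L || length(y1) < 2L) {
        return(list(detected = NA, f_hat = NULL))
      }
      tt <- stats::t.test(y1, y0)
      pvals[j] <- tt$p.value
      f_hat[j] <- mean(y1) - mean(y0)
    }
    list(detected = any(stats::p.adjust(pvals, "bonferroni") < alpha),
         f_hat = f_hat)
  }
}

detector_registry <- function() {
  list(oracle = detector_oracle(), ttest = detector_ttest())
}

#' Look up a bundled detector by name
#'
#' @param name `"oracle"` or `"ttest"`, or a detector function passed through
#'   unchanged.
#' @return A detector function.
#' @export
get_detector <- function(name) {
  if (is.function(name)) return(name)
  reg <- detector_registry()
  if (!name %in% names(reg)) {
    stop("unknown detector '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}
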