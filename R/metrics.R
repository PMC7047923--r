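#' Trend-recovery performance metrics
#'
#' Continuous metrics comparing an estimated differential-abundance trend
#' `f_hat` to the true trend `f_true` at a common set of timepoints:
#'
#' * `cosine_similarity()`: `dot(f_hat, f_true) / (||f_hat|| * ||f_true||)`,
#'   in `[-1, 1]`. Comparable across different numbers of timepoints but
#'   weakly discriminant near the boundaries.
#' * `euclidean_distance()`: `||f_hat - f_true||`, in `[0, Inf)`. Strongly
#'   influenced by the number of timepoints, so not comparable across
#'   different grid lengths.
#' * `normalized_euclidean()`: the distance between the unit vectors
#'   `f_hat / ||f_hat||` and `f_true / ||f_true||`, in `[0, 2]`; comparable
#'   across grid lengths. Satisfies
#'   `normalized_euclidean^2 = 2 * (1 - cosine_similarity)`.
#'
#' Cosine similarity and the normalized distance are undefined when either
#' vector has zero norm (e.g. a truly null trend); that raises an error
#' rather than a silent guess.
#'
#' @param f_hat Estimated trend values at the grid.
#' @param f_true True trend values at the same grid (same length).
#' @return A single number in the metric's range.
#' @examples
#' f <- c(0, 1, 2, 3)
#' cosine_similarity(2 * f, f)      # 1
#' euclidean_distance(c(3, 0), c(0, 4))  # 5
#' normalized_euclidean(-f, f)      # 2
#' @name trend_metrics
NULL

check_comparison <- function(f_hat, f_true) {
  if (!is.numeric(f_hat) || !is.numeric(f_true)) {
    stop("trend vectors must be numeric", call. = FALSE)
  }
  if (length(f_hat) != length(f_true) || length(f_hat) < 1L) {
    stop("estimated and true trends must have equal length >= 1",
         call. = FALSE)
  }
  if (anyNA(f_hat) || anyNA(f_true)) {
    stop("trend vectors must not contain missing values", call. = FALSE)
  }
}

require_nonzero_norm <- function(x, what) {
  n <- sqrt(sum(x^2))
  if (n == 0) {
    stop("undefined metric: ", what, " has zero norm", call. = FALSE)
  }
  n
}

#' @rdname trend_metrics
#' @export
cosine_similarity <- function(f_hat, f_true) {
  check_comparison(f_hat, f_true)
  nh <- require_nonzero_norm(f_hat, "estimated trend")
  nt <- require_nonzero_norm(f_true, "true trend")
  sum(f_hat * f_true) / (nh * nt)
}

#' @rdname trend_metrics
#' @export
euclidean_distance <- function(f_hat, f_true) {
  check_comparison(f_hat, f_true)
  sqrt(sum((f_hat - f_true)^2))
}

#' @rdname trend_metrics
#' @export
normalized_euclidean <- function(f_hat, f_true) {
  check_comparison(f_hat, f_true)
  nh <- require_nonzero_norm(f_hat, "estimated trend")
  nt <- require_nonzero_norm(f_true, "true trend")
  sqrt(sum((f_hat / nh - f_true / nt)^2))
}

#' Detection sensitivity and specificity over simulation repetitions
#'
#' Binary summaries of a detector across repeated simulations. Sensitivity is
#' the fraction of repetitions with a truly differential trend in which *any*
#' differential abundance was detected at any timepoint; specificity is the
#' fraction of repetitions with a truly null trend in which *no* differential
#' abundance was detected at any timepoint. Repetitions where the estimator
#' returned no result are excluded from the denominator (pass them already
#' filtered, or use the `estimate_missing` flag in [run_sweep()] results).
#'
#' @param detected Logical vector: was any differential abundance reported?
#' @param truth_is_diff Logical vector, same length: was the true trend
#'   non-null?
#' @return A list with `estimate` (the fraction), `numerator`, and
#'   `denominator`. Errors when no repetition is eligible.
#' @examples
#' sensitivity(detected = c(TRUE, TRUE, FALSE), truth_is_diff = rep(TRUE, 3))
#' @export
sensitivity <- function(detected, truth_is_diff) {
  detection_rate(detected, truth_is_diff, positive = TRUE)
}

#' @rdname sensitivity
#' @export
specificity <- function(detected, truth_is_diff) {
  detection_rate(detected, truth_is_diff, positive = FALSE)
}

detection_rate <- function(detected, truth_is_diff, positive) {
  stopifnot(is.logical(detected), is.logical(truth_is_diff),
            length(detected) == length(truth_is_diff))
  keep <- !is.na(detected) & truth_is_diff == positive
  denom <- sum(keep)
  if (denom == 0L) {
    stop("undefined metric: no eligible repetitions with truth_is_diff = ",
         positive, call. = FALSE)
  }
  num <- if (positive) sum(detected[keep]) else sum(!detected[keep])
  list(estimate = num / denom, numerator = num, denominator = denom)
}
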