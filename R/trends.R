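#' Specify a mean differential-abundance trend
#'
#' A trend spec describes the time-varying difference `f(t)` added to the
#' control-group mean to form the treatment-group mean. Supported families:
#'
#' * `"none"`: `f(t) = 0` everywhere (no differential abundance).
#' * `"linear"`, `"quadratic"`, `"cubic"`: polynomial
#'   `f(t) = beta0 + beta1*t + ... + betap*t^p` with `p + 1` coefficients.
#' * `"oscillating_M"`, `"oscillating_W"`: piecewise-linear spike-and-decay
#'   trends through three inflection points `ip = (IP1, IP2, IP3)`. The curve
#'   follows `beta0 + beta1*t` up to `IP1`, reaching `v = beta0 + beta1*IP1`,
#'   is forced to exactly zero at `IP2`, returns to `v` at `IP3`, and decays
#'   to zero at the end of the time interval. The sign of `beta1` picks the
#'   shape: positive gives an "M" (initial spike up), negative a "W".
#'   Absolute-value shapes are obtained by placing `IP2` and `IP3` beyond the
#'   end of the interval.
#' * `"L_up"`: hockey stick, flat at zero before the single inflection point
#'   `ip`, then linearly increasing with slope `beta1 > 0`:
#'   `f(t) = beta1 * (t - IP)` for `t >= IP`.
#' * `"L_down"`: hockey stick starting at `beta0 > 0` and decreasing with
#'   slope `beta1 < 0` until it hits zero at the implied inflection point
#'   `IP = -beta0 / beta1`, flat at zero afterwards.
#'
#' @param form Trend family, one of the strings above.
#' @param beta Numeric coefficient vector (abundance units). Length depends on
#'   the family: 2 for linear and oscillating, 3 quadratic, 4 cubic, 1 for
#'   `L_up`, 2 for `L_down`; ignored for `"none"`.
#' @param ip Numeric inflection points (time units): 3 strictly increasing
#'   values for oscillating forms, 1 value for `L_up`, none otherwise
#'   (`L_down` implies its own).
#' @return An object of class `trend_spec`.
#' @seealso [validate_trend()], [evaluate_trend()]
#' @examples
#' trend_spec("quadratic", beta = c(0, 3, -0.5))
#' trend_spec("L_up", beta = 0.5, ip = 5)
#' @export
trend_spec <- function(form = c("none", "linear", "quadratic", "cubic",
                                "oscillating_M", "oscillating_W",
                                "L_up", "L_down"),
                       beta = numeric(), ip = numeric()) {
  form <- match.arg(form)
  spec <- structure(
    list(form = form, beta = as.numeric(beta), ip = as.numeric(ip)),
    class = "trend_spec"
  )
  viol <- validate_trend(spec)
  if (length(viol) > 0L) {
    stop("invalid trend spec: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  spec
}

#' @export
print.trend_spec <- function(x, ...) {
  cat("<trend_spec>", x$form, "\n")
  if (length(x$beta)) cat("  beta:", paste(x$beta, collapse = ", "), "\n")
  if (length(x$ip)) cat("  ip:  ", paste(x$ip, collapse = ", "), "\n")
  if (x$form == "L_down") cat("  implied IP:", implied_ip(x), "\n")
  invisible(x)
}

#' Implied inflection point of an L_down trend
#'
#' The time at which `beta0 + beta1 * t` crosses zero, `-beta0 / beta1`.
#'
#' @param spec A `trend_spec` with `form = "L_down"`.
#' @return The implied inflection point (time units).
#' @export
implied_ip <- function(spec) {
  stopifnot(inherits(spec, "trend_spec"))
  if (spec$form != "L_down") {
    stop("implied_ip() is defined only for L_down trends", call. = FALSE)
  }
  -spec$beta[1L] / spec$beta[2L]
}

#' Validate a trend specification
#'
#' Checks structural constraints of the family (coefficient counts, sign
#' restrictions, inflection-point ordering) and, when a time interval is
#' supplied, interval constraints: hockey-stick inflection points must lie
#' strictly inside `(t1, tq)`, and oscillating trends require `IP3 != tq`
#' unless the absolute-value configuration (`IP1` inside the interval,
#' `IP2, IP3 > tq`) is used.
#'
#' @param spec A `trend_spec` (or a bare list with `form`, `beta`, `ip`).
#' @param t_interval Optional numeric pair `(t1, tq)` with `t1 < tq`.
#' @return A character vector of violations; `character(0)` when valid.
#' @examples
#' validate_trend(trend_spec("L_down", beta = c(2, -0.5)), c(0, 10)) # ok
#' validate_trend(trend_spec("L_down", beta = c(2, -0.5)), c(0, 3))  # IP = 4
#' @export
validate_trend <- function(spec, t_interval = NULL) {
  form <- spec$form
  beta <- spec$beta
  ip <- spec$ip
  v <- character()
  add <- function(msg) v <<- c(v, msg)

  if (!is.null(t_interval)) {
    if (length(t_interval) != 2L || !is.numeric(t_interval) ||
        t_interval[1L] >= t_interval[2L]) {
      stop("t_interval must be a numeric pair (t1, tq) with t1 < tq",
           call. = FALSE)
    }
  }
  if (any(!is.finite(beta))) add("beta coefficients must be finite")
  if (any(!is.finite(ip))) add("inflection points must be finite")
  if (length(v) > 0L) return(v)

  n_beta <- c(linear = 2L, quadratic = 3L, cubic = 4L)
  if (form %in% names(n_beta) && length(beta) != n_beta[[form]]) {
    add(sprintf("%s form requires %d coefficients (got %d)",
                form, n_beta[[form]], length(beta)))
  }
  if (form %in% c("oscillating_M", "oscillating_W")) {
    if (length(beta) != 2L) {
      add("oscillating forms require 2 coefficients (beta0, beta1)")
    } else if (form == "oscillating_M" && beta[2L] <= 0) {
      add("oscillating_M requires a positive initial slope (beta1 > 0)")
    } else if (form == "oscillating_W" && beta[2L] >= 0) {
      add("oscillating_W requires a negative initial slope (beta1 < 0)")
    }
    if (length(ip) != 3L) {
      add("oscillating forms require 3 inflection points")
    } else if (is.unsorted(ip, strictly = TRUE)) {
      add("inflection points must satisfy IP1 < IP2 < IP3")
    } else if (!is.null(t_interval)) {
      t1 <- t_interval[1L]; tq <- t_interval[2L]
      degenerate <- ip[1L] > t1 && ip[1L] < tq && ip[2L] > tq && ip[3L] > tq
      if (!degenerate) {
        if (ip[3L] == tq) {
          add("IP3 must differ from the interval endpoint tq")
        }
        if (ip[1L] <= t1 || ip[3L] >= tq) {
          add(paste("inflection points must lie inside the time interval",
                    "(or use IP2, IP3 beyond tq for an absolute-value trend)"))
        }
      }
    }
  }
  if (form == "L_up") {
    if (length(beta) != 1L) {
      add("L_up requires a single slope coefficient")
    } else if (beta[1L] <= 0) {
      add("L_up slope must be positive")
    }
    if (length(ip) != 1L) {
      add("L_up requires one inflection point")
    } else if (!is.null(t_interval) &&
               (ip[1L] <= t_interval[1L] || ip[1L] >= t_interval[2L])) {
      add(sprintf("IP = %g outside interval (%g, %g)",
                  ip[1L], t_interval[1L], t_interval[2L]))
    }
  }
  if (form == "L_down") {
    if (length(beta) != 2L) {
      add("L_down requires coefficients (beta0, beta1)")
    } else {
      if (beta[1L] <= 0) add("L_down requires beta0 > 0")
      if (beta[2L] >= 0) add("L_down requires a negative slope (beta1 < 0)")
      if (beta[1L] > 0 && beta[2L] < 0 && !is.null(t_interval)) {
        ip_imp <- -beta[1L] / beta[2L]
        if (ip_imp <= t_interval[1L] || ip_imp >= t_interval[2L]) {
          add(sprintf("implied IP = %g outside interval (%g, %g)",
                      ip_imp, t_interval[1L], t_interval[2L]))
        }
      }
    }
  }
  v
}

#' Evaluate a trend at a set of timepoints
#'
#' Computes `f(t)` pointwise for the family described by `spec`. Boundary
#' conventions are left-closed/right-open: `L_up` includes `t = IP` in the
#' increasing region (both branches give 0 there), `L_down` includes its
#' implied inflection point in the flat region, and oscillating segments are
#' `[IPk, IPk+1)`.
#'
#' @param spec A `trend_spec`.
#' @param timepoints Sorted numeric vector of evaluation times. Need not be a
#'   design grid; asynchronous schedules reuse this code path.
#' @param t_interval Time interval `(t1, tq)` the trend is defined over;
#'   defaults to `range(timepoints)`. Oscillating forms use `tq` as the
#'   final anchor where the trend returns to zero. Interval constraints
#'   (inflection points inside the interval) are enforced only when
#'   `t_interval` is supplied explicitly, so a spec can be evaluated at
#'   arbitrary probe points.
#' @return Numeric vector `f(timepoints)`.
#' @examples
#' evaluate_trend(trend_spec("L_up", beta = 0.5, ip = 5), c(0, 5, 10))
#' @export
evaluate_trend <- function(spec, timepoints, t_interval = range(timepoints)) {
  stopifnot(is.numeric(timepoints), length(timepoints) >= 1L)
  if (is.unsorted(timepoints)) {
    stop("timepoints must be sorted ascending", call. = FALSE)
  }
  explicit_interval <- !missing(t_interval)
  viol <- validate_trend(spec, if (explicit_interval) t_interval else NULL)
  if (length(viol) > 0L) {
    stop("invalid trend spec: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  t <- as.numeric(timepoints)
  beta <- spec$beta
  switch(spec$form,
    none = rep(0, length(t)),
    linear = ,
    quadratic = ,
    cubic = {
      p <- length(beta) - 1L
      drop(outer(t, 0:p, `^`) %*% beta)
    },
    L_up = ifelse(t >= spec$ip[1L], beta[1L] * (t - spec$ip[1L]), 0),
    L_down = {
      ip_imp <- implied_ip(spec)
      ifelse(t < ip_imp, beta[1L] + beta[2L] * t, 0)
    },
    oscillating_M = ,
    oscillating_W = {
      ip1 <- spec$ip[1L]; ip2 <- spec$ip[2L]; ip3 <- spec$ip[3L]
      tq <- t_interval[2L]
      v <- beta[1L] + beta[2L] * ip1
      out <- numeric(length(t))
      seg1 <- t < ip1
      seg2 <- t >= ip1 & t < ip2
      seg3 <- t >= ip2 & t < ip3
      seg4 <- t >= ip3
      out[seg1] <- beta[1L] + beta[2L] * t[seg1]
      out[seg2] <- v * (ip2 - t[seg2]) / (ip2 - ip1)
      out[seg3] <- v * (t[seg3] - ip2) / (ip3 - ip2)
      out[seg4] <- v * (tq - t[seg4]) / (tq - ip3)
      out
    }
  )
}
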