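#' Specify left truncation of the sampling distribution
#'
#' Microbiome abundances (after log-type transformation) are non-negative, so
#' the simulator can draw from a left-truncated multivariate normal instead of
#' the unrestricted one. Truncation is applied per subject block with a hybrid
#' scheme: when the estimated probability that a whole block clears the bound,
#' `p_acpt = P(Y > a)`, exceeds `acceptance_threshold`, the block is rejection
#' sampled (redrawn until all coordinates exceed `a`); otherwise rejection is
#' impractically slow and values below `a` are censored to `a` (point
#' imputation).
#'
#' @param enabled Impose the truncation (`TRUE`, the default) or draw from the
#'   plain multivariate normal.
#' @param a Left-truncation bound (abundance units); `0` gives zero
#'   truncation.
#' @param acceptance_threshold Minimum acceptance probability for rejection
#'   sampling, in `(0, 1]`; blocks below it fall back to censoring.
#'   Default `0.1`.
#' @param pilot_draws Monte Carlo pilot sample size used to estimate the
#'   per-block acceptance probability; `>= 100`, default `1000`.
#' @return An object of class `trunc_spec`.
#' @export
truncation_spec <- function(enabled = TRUE, a = 0,
                            acceptance_threshold = 0.1, pilot_draws = 1000L) {
  stopifnot(is.logical(enabled), length(enabled) == 1L,
            is.numeric(a), length(a) == 1L, is.finite(a))
  if (!is.numeric(acceptance_threshold) || length(acceptance_threshold) != 1L ||
      acceptance_threshold <= 0 || acceptance_threshold > 1) {
    stop("acceptance_threshold must lie in (0, 1]", call. = FALSE)
  }
  pilot_draws <- as.integer(pilot_draws)
  if (pilot_draws < 100L) stop("pilot_draws must be >= 100", call. = FALSE)
  structure(list(enabled = enabled, a = a,
                 acceptance_threshold = acceptance_threshold,
                 pilot_draws = pilot_draws),
            class = "trunc_spec")
}

chol_or_fail <- function(sigma_block) {
  r <- try(chol(sigma_block), silent = TRUE)
  if (inherits(r, "try-error")) {
    stop("covariance block is not positive-definite (Cholesky failed); ",
         "check sigma/rho", call. = FALSE)
  }
  r
}

# One or more draws from N(mu, Sigma) given the upper Cholesky factor R of
# Sigma: columns of mu + t(R) %*% Z.
draw_mvn <- function(mu, chol_upper, n = 1L) {
  q <- length(mu)
  z <- matrix(stats::rnorm(q * n), q, n)
  mu + crossprod(chol_upper, z)
}

#' Estimate the per-block acceptance probability
#'
#' Monte Carlo estimate of `P(all q coordinates > a)` for one subject block,
#' from `pilot_draws` draws of the unconstrained multivariate normal. This is
#' the quantity that decides between rejection sampling and censoring.
#'
#' @param mu_block Mean vector of the block (length `q`).
#' @param sigma_block `q x q` positive-definite covariance.
#' @param a Left-truncation bound.
#' @param pilot_draws Number of pilot draws.
#' @return Estimated acceptance probability in `[0, 1]`.
#' @examples
#' set.seed(1)
#' estimate_acceptance(c(10, 10), diag(2), a = 0)  # ~ 1
#' @export
estimate_acceptance <- function(mu_block, sigma_block, a = 0,
                                pilot_draws = 1000L) {
  stopifnot(length(mu_block) == nrow(sigma_block))
  r <- chol_or_fail(sigma_block)
  y <- draw_mvn(mu_block, r, pilot_draws)
  mean(colSums(y > a) == length(mu_block))
}

#' Draw from the block multivariate (truncated) normal
#'
#' Samples one observation vector of length `N = sum(q_i)` from
#' `N(mu, bdiag(Sigma_1, ..., Sigma_n))`, optionally restricted to values
#' above the truncation bound. With truncation enabled, each block uses
#' rejection sampling when its estimated acceptance probability exceeds the
#' threshold and censoring (values below `a` set to `a`) otherwise. Blocks
#' sharing the same mean vector and covariance share one acceptance estimate
#' and hence one sampling mode, so in a standard two-arm design each arm is
#' sampled in a single mode.
#'
#' @param mu_blocks List of per-subject mean vectors.
#' @param sigma_blocks List of per-subject covariance matrices (a
#'   [block_covariance()] result works directly), or a single matrix recycled
#'   across subjects.
#' @param trunc A [truncation_spec()].
#' @param max_attempts Hard cap on total redraws per block in rejection mode;
#'   exceeding it aborts with a diagnostic rather than silently degrading.
#' @return A list with `y` (numeric vector of length `N`) and `modes`
#'   (character vector, one of `"rejection"`, `"censored"`, `"untruncated"`
#'   per block).
#' @export
sample_truncated_mvn <- function(mu_blocks, sigma_blocks, trunc = truncation_spec(),
                                 max_attempts = 1e5) {
  stopifnot(inherits(trunc, "trunc_spec"), is.list(mu_blocks))
  if (is.matrix(sigma_blocks)) {
    sigma_blocks <- rep(list(sigma_blocks), length(mu_blocks))
  }
  if (length(sigma_blocks) != length(mu_blocks)) {
    stop("mu_blocks and sigma_blocks must have the same length", call. = FALSE)
  }
  qs <- lengths(mu_blocks)
  bad <- which(qs != vapply(sigma_blocks, nrow, integer(1)))
  if (length(bad) > 0L) {
    stop("block dimension mismatch at subject ", bad[1L], call. = FALSE)
  }

  n_blocks <- length(mu_blocks)
  # cache Cholesky factors per distinct covariance block
  sig_key <- vapply(sigma_blocks, function(s) paste(s, collapse = ","),
                    character(1))
  chol_cache <- lapply(sigma_blocks[!duplicated(sig_key)], chol_or_fail)
  names(chol_cache) <- sig_key[!duplicated(sig_key)]

  if (!trunc$enabled) {
    y <- vector("list", n_blocks)
    for (i in seq_len(n_blocks)) {
      y[[i]] <- drop(draw_mvn(mu_blocks[[i]], chol_cache[[sig_key[i]]]))
    }
    return(list(y = unlist(y, use.names = FALSE),
                modes = rep("untruncated", n_blocks)))
  }

  a <- trunc$a
  # one acceptance estimate per distinct (mean block, covariance block) pair
  blk_key <- paste(vapply(mu_blocks, function(m) paste(m, collapse = ","),
                          character(1)),
                   sig_key, sep = "|")
  first <- which(!duplicated(blk_key))
  p_acpt <- vapply(first, function(i) {
    estimate_acceptance(mu_blocks[[i]], sigma_blocks[[i]], a = a,
                        pilot_draws = trunc$pilot_draws)
  }, numeric(1))
  names(p_acpt) <- blk_key[first]

  y <- vector("list", n_blocks)
  modes <- character(n_blocks)
  for (i in seq_len(n_blocks)) {
    r <- chol_cache[[sig_key[i]]]
    mu <- mu_blocks[[i]]
    if (p_acpt[[blk_key[i]]] > trunc$acceptance_threshold) {
      attempts <- 0L
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop("rejection sampling exceeded ", max_attempts,
               " attempts for a subject block (estimated acceptance ",
               signif(p_acpt[[blk_key[i]]], 3),
               "); lower acceptance_threshold to allow censoring or ",
               "reconsider the design", call. = FALSE)
        }
        cand <- drop(draw_mvn(mu, r))
        if (all(cand > a)) break
      }
      y[[i]] <- cand
      modes[i] <- "rejection"
    } else {
      cand <- drop(draw_mvn(mu, r))
      cand[cand < a] <- a
      y[[i]] <- cand
      modes[i] <- "censored"
    }
  }
  list(y = unlist(y, use.names = FALSE), modes = modes)
}
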