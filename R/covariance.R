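#' Specify the within-subject covariance structure
#'
#' Each subject's repeated measurements share a `q x q` covariance matrix
#' `Sigma_i = sigma^2 * Omega(rho)`, where `Omega` is one of three
#' correlation structures indexed by measurement order:
#'
#' * `"ar1"`: first-order autoregressive, correlation `rho^|j - j'|` between
#'   the j-th and j'-th measurements; requires `rho` in `(-1, 1)`.
#' * `"compound"`: compound symmetry (exchangeable), correlation `rho`
#'   between every pair; restricted to `rho` in `[0, 1)` so the matrix is
#'   positive-definite for every block size.
#' * `"independent"`: uncorrelated repeated measurements; `rho` is ignored.
#'
#' Observations from different subjects are always independent, so the full
#' covariance over all `N` observations is block diagonal.
#'
#' @param structure One of `"ar1"`, `"compound"`, `"independent"`.
#' @param sigma Global standard deviation (abundance units), `> 0`.
#' @param rho Correlation parameter.
#' @return An object of class `cov_spec`.
#' @seealso [subject_covariance()], [block_covariance()]
#' @export
cov_spec <- function(structure = c("ar1", "compound", "independent"),
                     sigma = 1, rho = 0) {
  structure <- match.arg(structure)
  stopifnot(is.numeric(sigma), length(sigma) == 1L,
            is.numeric(rho), length(rho) == 1L)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive finite number", call. = FALSE)
  }
  if (structure == "ar1" && (rho <= -1 || rho >= 1)) {
    stop("ar1 requires rho in (-1, 1)", call. = FALSE)
  }
  if (structure == "compound" && (rho < 0 || rho >= 1)) {
    stop("compound symmetry requires rho in [0, 1); negative exchangeable ",
         "correlation is block-size dependent and not supported",
         call. = FALSE)
  }
  structure(list(structure = structure, sigma = sigma, rho = rho),
            class = "cov_spec")
}

#' @export
print.cov_spec <- function(x, ...) {
  cat("<cov_spec>", x$structure, " sigma =", x$sigma,
      if (x$structure != "independent") paste(" rho =", x$rho), "\n")
  invisible(x)
}

#' Per-subject covariance matrix
#'
#' Builds the `q x q` covariance block for one subject under the given
#' structure: `sigma^2 * rho^|j - j'|` (AR(1)), `sigma^2 * rho` off-diagonal
#' (compound symmetry), or `sigma^2 * I` (independent).
#'
#' @param spec A [cov_spec()].
#' @param q Number of repeated measurements, `>= 1`.
#' @return A `q x q` symmetric numeric matrix.
#' @examples
#' subject_covariance(cov_spec("ar1", sigma = 1, rho = 0.5), q = 3)
#' @export
subject_covariance <- function(spec, q) {
  stopifnot(inherits(spec, "cov_spec"))
  q <- as.integer(q)
  if (q < 1L) stop("q must be >= 1", call. = FALSE)
  omega <- switch(spec$structure,
    ar1 = spec$rho ^ abs(outer(seq_len(q), seq_len(q), `-`)),
    compound = {
      m <- matrix(spec$rho, q, q)
      diag(m) <- 1
      m
    },
    independent = diag(q)
  )
  spec$sigma^2 * omega
}

#' Block-diagonal covariance over all subjects
#'
#' Represents `Sigma = bdiag(Sigma_1, ..., Sigma_n)` as a list of per-subject
#' blocks (class `block_cov`). Cross-subject covariances are identically zero,
#' so the dense matrix is never needed for sampling; use [as.matrix()] to
#' assemble it for inspection at small `N`.
#'
#' @param spec A [cov_spec()].
#' @param q_per_subject Integer vector of repeated-measurement counts, one
#'   per subject (all `>= 1`).
#' @return A `block_cov` object: a list of `q_i x q_i` matrices with the
#'   total dimension `N = sum(q_i)` as an attribute.
#' @examples
#' as.matrix(block_covariance(cov_spec("independent"), c(2, 2)))
#' @export
block_covariance <- function(spec, q_per_subject) {
  q_per_subject <- as.integer(q_per_subject)
  if (length(q_per_subject) < 1L || any(q_per_subject < 1L)) {
    stop("q_per_subject must contain at least one value, all >= 1",
         call. = FALSE)
  }
  # identical q values share one block object
  uq <- sort(unique(q_per_subject))
  proto <- lapply(uq, function(q) subject_covariance(spec, q))
  names(proto) <- as.character(uq)
  blocks <- proto[as.character(q_per_subject)]
  names(blocks) <- NULL
  structure(blocks,
            n_total = sum(q_per_subject),
            spec = spec,
            class = "block_cov")
}

#' @export
print.block_cov <- function(x, ...) {
  cat("<block_cov>", length(x), "subject blocks, N =",
      attr(x, "n_total"), "\n")
  invisible(x)
}

#' Assemble a block covariance into a dense matrix
#'
#' @param x A `block_cov` object.
#' @param ... Unused.
#' @return Dense `N x N` matrix with zero cross-subject entries.
#' @export
as.matrix.block_cov <- function(x, ...) {
  n_total <- attr(x, "n_total")
  out <- matrix(0, n_total, n_total)
  at <- 0L
  for (b in x) {
    q <- nrow(b)
    idx <- at + seq_len(q)
    out[idx, idx] <- b
    at <- at + q
  }
  out
}
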