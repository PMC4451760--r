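#' Finite-sample correction factors
#'
#' The dimensionless factors entering the bias-corrected estimators and their
#' variance, for \code{T} trials per condition, \code{N} neurons and stimulus
#' separation \code{dtheta}. Under Gaussian response variability the pooled
#' sample covariance follows a Wishart distribution with 2(T-1) degrees of
#' freedom, and the expectation of its inverse exceeds the true inverse
#' covariance by the factor (2T-2)/(2T-N-3); \code{c_cov} is the reciprocal
#' scaling that makes \code{c_cov * solve(S)} unbiased. \code{gamma} is the
#' variance inflation of the finite-difference tuning derivative; \code{alpha}
#' and \code{beta} parameterize the covariance of the inverse-Wishart matrix
#' elements.
#'
#' @param n_trials trials per condition (T).
#' @param n_neurons population size (N).
#' @param dtheta stimulus separation.
#' @return list with \code{c_cov = (2T-N-3)/(2T-2)},
#'   \code{gamma = 2/(T dtheta^2)},
#'   \code{alpha = 2/((2T-N-2)(2T-N-5))},
#'   \code{beta = (2T-N-3)/((2T-N-2)(2T-N-5))}.
#' @export
correction_factors <- function(n_trials, n_neurons, dtheta) {
  T <- n_trials; N <- n_neurons
  stopifnot(T >= 2, N >= 1, dtheta > 0)
  d2 <- 2 * T - N - 2
  d5 <- 2 * T - N - 5
  list(c_cov = (2 * T - N - 3) / (2 * T - 2),
       gamma = 2 / (T * dtheta^2),
       alpha = if (d2 != 0 && d5 != 0) 2 / (d2 * d5) else Inf,
       beta  = if (d2 != 0 && d5 != 0) (2 * T - N - 3) / (d2 * d5) else Inf)
}

# symmetric solve used by every estimator: enforce symmetry, fail with a
# regime-aware message when the pooled covariance is rank deficient
.sym_solve <- function(S, b, n_trials, n_neurons) {
  S <- (S + t(S)) / 2
  out <- tryCatch(solve(S, b), error = function(e) e)
  if (inherits(out, "error")) {
    stop(sprintf(paste0(
      "pooled covariance is singular (N = %d vs 2(T-1) = %d): the direct ",
      "estimators require N <= 2(T-1) and are unusable for T <= (N+2)/2"),
      n_neurons, 2 * (n_trials - 1)), call. = FALSE)
  }
  out
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with integer tags (e.g. trial count and replicate
#' index) through a fixed linear-congruential scramble, so that per-replicate
#' random streams are reproducible and independent of execution order.
#' The result is always a valid 32-bit R seed.
#'
#' @param master integer master seed.
#' @param ... integer tags identifying the sub-stream.
#' @return an integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, ...) {
  tags <- c(...)
  s <- as.numeric(master) %% 2147483647
  primes <- c(2654435761, 40503, 2246822519, 3266489917, 668265263)
  for (i in seq_along(tags)) {
    p <- primes[((i - 1) %% length(primes)) + 1]
    s <- (s * 69069 + as.numeric(tags[i]) * p + 1013904223) %% 2147483647
  }
  as.integer(s %% 2147483646 + 1)
}
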