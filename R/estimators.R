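#' Information estimate container
#'
#' Scalar linear Fisher information value (stimulus-units^-2) with its method
#' tag, the analytic sampling variance when one is available, and the data
#' geometry it was computed from. Bias-corrected values may legitimately be
#' negative in noisy regimes; they are never clipped.
#'
#' @param value information value.
#' @param method one of "naive", "bias_corrected", "shuffle", "crossed",
#'   "diag", "decoder_validation", "decoder_training", "ground_truth".
#' @param n_trials,n_neurons,dtheta data geometry.
#' @param analytic_variance analytic sampling variance, or NA.
#' @param degenerate logical flag for degenerate denominators (crossed/diag
#'   estimators at very small T).
#' @return object of class \code{"info_estimate"}.
#' @export
info_estimate <- function(value, method, n_trials, n_neurons, dtheta,
                          analytic_variance = NA_real_, degenerate = FALSE) {
  method <- match.arg(method, c("naive", "bias_corrected", "shuffle",
                                "crossed", "diag", "decoder_validation",
                                "decoder_training", "ground_truth"))
  if (!is.na(analytic_variance) && analytic_variance < 0)
    stop("analytic_variance must be non-negative or NA")
  structure(
    list(value = as.numeric(value), method = method,
         analytic_variance = as.numeric(analytic_variance),
         n_trials = n_trials, n_neurons = n_neurons, dtheta = dtheta,
         degenerate = isTRUE(degenerate)),
    class = "info_estimate")
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf("Linear Fisher information (%s): %.6g", x$method, x$value))
  if (!is.na(x$analytic_variance))
    cat(sprintf("  [analytic SD %.3g]", sqrt(x$analytic_variance)))
  if (x$degenerate) cat("  [degenerate]")
  cat(sprintf("\n  T = %d trials/condition, N = %d neurons, dtheta = %g\n",
              x$n_trials, x$n_neurons, x$dtheta))
  invisible(x)
}

#' @export
as.numeric.info_estimate <- function(x, ...) x$value

#' Naive direct estimator of linear Fisher information
#'
#' Plugs the empirical moments straight into the defining quadratic form
#' I = dmu' S^-1 dmu (derivatives per unit dtheta). Because the covariance is
#' inverted and the derivative squared, this estimator is biased upward: its
#' expectation is (2T-2)/(2T-N-3) * (I + 2N/(T dtheta^2)) under Gaussian
#' variability. Use \code{\link{bc_info}} for the unbiased version.
#'
#' @param m a \code{\link{moment_summary}} (or \code{\link{trial_set}}, which
#'   is summarized first).
#' @return an \code{\link{info_estimate}} with method "naive".
#' @seealso \code{\link{bc_info}}
#' @export
naive_info <- function(m) {
  m <- as_moment_summary(m)
  x <- .sym_solve(m$S_pooled, m$dmu_dtheta, m$n_trials, m$n_neurons)
  info_estimate(sum(m$dmu_dtheta * x), "naive",
                m$n_trials, m$n_neurons, m$dtheta)
}

as_moment_summary <- function(m) {
  if (inherits(m, "trial_set")) m <- summarize_trials(m)
  stopifnot(inherits(m, "moment_summary"))
  m
}

#' Bias-corrected direct estimator of linear Fisher information
#'
#' The unbiased estimator
#' \deqn{\hat I_{bc} = \frac{d\mu}{d\theta}^T S^{-1} \frac{d\mu}{d\theta}
#'   \cdot \frac{2T-N-3}{2T-2} - \frac{2N}{T\,d\theta^2}}
#' which removes both the inverse-Wishart bias of the inverted pooled sample
#' covariance and the derivative-squaring bias. Under Gaussian response
#' variability its expectation equals the true linear Fisher information for
#' any T > (N+2)/2. The analytic sampling variance is attached
#' (plug-in form, see \code{\link{bc_info_variance}}) when T > (N+5)/2.
#'
#' The corrected value may occasionally be negative when the estimate is very
#' noisy; it is returned as-is, with a warning when its magnitude is below
#' the analytic standard deviation.
#'
#' @inheritParams naive_info
#' @param warn_noisy emit a warning when |value| < analytic SD (default TRUE).
#' @return an \code{\link{info_estimate}} with method "bias_corrected".
#' @export
bc_info <- function(m, warn_noisy = TRUE) {
  m <- as_moment_summary(m)
  T <- m$n_trials; N <- m$n_neurons
  if (T <= (N + 2) / 2)
    stop(sprintf(paste0("bias-corrected estimation is unusable for T <= (N+2)/2 ",
                        "(T = %d, N = %d): the pooled covariance is singular"), T, N))
  cf <- correction_factors(T, N, m$dtheta)
  nv <- naive_info(m)$value
  val <- nv * cf$c_cov - N * cf$gamma
  avar <- if (2 * T - N - 5 > 0) {
    bc_info_variance(max(val, 0), T, N, m$dtheta)
  } else NA_real_    # divergent-variance regime (N+2)/2 < T <= (N+5)/2
  if (warn_noisy && !is.na(avar) && abs(val) < sqrt(avar))
    warning(sprintf("estimate %.4g is smaller in magnitude than its analytic SD %.4g",
                    val, sqrt(avar)))
  info_estimate(val, "bias_corrected", T, N, m$dtheta, analytic_variance = avar)
}

#' Analytic variance of the bias-corrected estimator
#'
#' Closed-form sampling variance of \code{\link{bc_info}} under Gaussian
#' variability:
#' \deqn{Var = \frac{2I^2}{2T-N-5}\left(1 + \frac{4(2T-3)}{T I d\theta^2}
#'   + \frac{4N(2T-3)}{T^2 I^2 d\theta^4}\right)}
#' evaluated in expanded form so that I = 0 gives the finite limit
#' 8N(2T-3) / ((2T-N-5) T^2 dtheta^4). The variance diverges for
#' T = (N+5)/2, the fundamental lower bound on the usable trial count.
#'
#' @param info true (or plug-in) information value, >= 0.
#' @param n_trials,n_neurons,dtheta data geometry.
#' @return the variance (scalar).
#' @export
bc_info_variance <- function(info, n_trials, n_neurons, dtheta) {
  T <- n_trials; N <- n_neurons
  if (2 * T - N - 5 <= 0)
    stop(sprintf(paste0("the variance of the bias-corrected estimator diverges ",
                        "for T = (N+5)/2 (here T = %s, N = %d)"),
                 format(T), N))
  if (info < 0) stop("info must be non-negative")
  2 / (2 * T - N - 5) *
    (info^2 + 4 * (2 * T - 3) * info / (T * dtheta^2) +
       4 * N * (2 * T - 3) / (T^2 * dtheta^4))
}

#' Bias-corrected estimator of the shuffled information
#'
#' Information of a fictitious independent population with the same marginal
#' statistics (correlations destroyed). Computed from the marginal variances
#' only — no data shuffling is performed:
#' \deqn{\hat I_{shuffle} = \sum_i \frac{(d\mu_i/d\theta)^2}{s_i^2}
#'   \cdot\frac{T-2}{T-1} - \frac{2N}{T d\theta^2}}
#' with \eqn{s_i^2 = (s_i^{+2} + s_i^{-2})/2}. The per-variance correction
#' factor (T-2)/(T-1) is the N = 1 specialization of the inverse-Wishart
#' correction (each marginal variance has 2(T-1) pooled degrees of freedom).
#'
#' @inheritParams naive_info
#' @return an \code{\link{info_estimate}} with method "shuffle".
#' @export
bc_info_shuffle <- function(m) {
  m <- as_moment_summary(m)
  T <- m$n_trials; N <- m$n_neurons
  if (T < 3) stop("the shuffle estimator requires T >= 3")
  s2 <- (diag(m$S_plus) + diag(m$S_minus)) / 2
  if (any(s2 <= 0))
    stop("zero marginal variance for neuron(s) ",
         paste(which(s2 <= 0), collapse = ", "))
  cf <- correction_factors(T, N, m$dtheta)
  val <- sum(m$dmu_dtheta^2 / s2) * (T - 2) / (T - 1) - N * cf$gamma
  info_estimate(val, "shuffle", T, N, m$dtheta)
}

# Shared core of the crossed (train on A, test on B) estimators.
# numerator_correction = 2N/(T dtheta^2) turns it into the diagonal-decoder
# variant, where A and B share tuning so the squared cross term is biased
# like the squared derivative in the plain estimator.
.crossed_core <- function(mA, mB, numerator_correction = 0, method = "crossed") {
  T <- mA$n_trials; N <- mA$n_neurons
  if (mB$n_neurons != N) stop("datasets A and B must have the same N")
  if (mB$n_trials != T) stop("datasets A and B must have the same T")
  if (abs(mA$dtheta - mB$dtheta) > 1e-12) stop("datasets A and B must share dtheta")
  if (2 * T - N - 5 <= 0)
    stop(sprintf("crossed estimation requires 2T - N - 5 > 0 (T = %d, N = %d)", T, N))
  cf <- correction_factors(T, N, mA$dtheta)
  SA <- (mA$S_pooled + t(mA$S_pooled)) / 2
  SAinv_hat <- cf$c_cov * .sym_solve(SA, diag(N), T, N)
  SB <- mB$S_pooled
  u <- SAinv_hat %*% mA$dmu_dtheta
  num <- (sum(mB$dmu_dtheta * u) - numerator_correction)^2
  den <- as.numeric(t(u) %*% SB %*% u)
  d2 <- 2 * T - N - 2; d5 <- 2 * T - N - 5
  trAB <- sum(SAinv_hat * t(SB))              # Tr(SAinv_hat %*% SB)
  lambda_hat <- cf$gamma *
    (1 + (2 * T - N - 1 + N * (2 * T - N - 3)) / (d2 * d5)) * trAB
  rho_hat <- cf$beta * trAB * bc_info(mA, warn_noisy = FALSE)$value
  scale <- 1 + (2 * T - N - 1) / (d2 * d5)
  # lambda_hat + rho_hat is the (plug-in) bias of the naive denominator, and
  # the remaining multiplicative bias is 1/scale; subtracting inside the
  # denominator and rescaling makes it unbiased
  den_corrected <- den - lambda_hat - rho_hat
  degenerate <- !is.finite(den_corrected) || den_corrected <= 0
  val <- if (degenerate) NA_real_ else num / den_corrected * scale
  info_estimate(val, method, T, N, mA$dtheta, degenerate = degenerate)
}

#' Bias-corrected crossed information estimator
#'
#' Estimates the information that the decoder optimal for dataset A extracts
#' from dataset B,
#' \eqn{I_{AB} = (f'_B{}^T \Sigma_A^{-1} f'_A)^2 /
#'   (f'_A{}^T \Sigma_A^{-1} \Sigma_B \Sigma_A^{-1} f'_A)},
#' with finite-sample corrections for the doubly inverted covariance of A
#' (inverse-Wishart moments) and for the derivative noise terms. Numerator
#' and denominator are bias-corrected separately; the residual bias of the
#' ratio is O(1/T) rather than O(N/T).
#'
#' If the corrected denominator is non-positive (possible at small T by
#' sampling noise) the estimate is returned with the \code{degenerate} flag
#' set and value NA rather than raising an error.
#'
#' @param mA,mB moment summaries (or trial sets) of datasets A (decoder
#'   source) and B (evaluation data); same N, T and dtheta.
#' @return an \code{\link{info_estimate}} with method "crossed".
#' @export
bc_info_crossed <- function(mA, mB) {
  .crossed_core(as_moment_summary(mA), as_moment_summary(mB),
                numerator_correction = 0, method = "crossed")
}

#' Bias-corrected diagonal-decoder information estimator
#'
#' Information recovered from the correlated population by a factorized
#' (correlation-blind) decoder: the crossed estimator with dataset A a
#' trial-shuffled copy of the data (so the decoder cannot model
#' correlations, but the shuffled covariance retains the residual
#' correlations of a finite shuffle) and dataset B the original data.
#' Because A and B share the tuning derivative, the squared numerator
#' receives the additional correction \code{- 2N/(T dtheta^2)} before
#' squaring.
#'
#' @param data a \code{\link{trial_set}}.
#' @param seed integer seed for the shuffle permutations.
#' @param n_shuffles number of independent shuffle realizations to average
#'   over (default 1).
#' @return an \code{\link{info_estimate}} with method "diag".
#' @export
bc_info_diag <- function(data, seed, n_shuffles = 1) {
  stopifnot(inherits(data, "trial_set"), n_shuffles >= 1)
  mB <- summarize_trials(data)
  corr <- 2 * mB$n_neurons / (mB$n_trials * mB$dtheta^2)
  ests <- lapply(seq_len(n_shuffles), function(k) {
    mA <- summarize_trials(shuffle_trials(data, derive_seed(seed, 211, k)))
    .crossed_core(mA, mB, numerator_correction = corr, method = "diag")
  })
  vals <- vapply(ests, function(e) e$value, numeric(1))
  info_estimate(mean(vals), "diag", mB$n_trials, mB$n_neurons, mB$dtheta,
                degenerate = any(vapply(ests, function(e) e$degenerate, logical(1))))
}
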