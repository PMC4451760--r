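#' Analytic ground truth of a simulated population
#'
#' Holds the analytic tuning values at the two conditions, the finite
#' difference derivative, the per-condition covariances and their average,
#' and the resulting true linear Fisher information
#' \eqn{I = f'^T \bar\Sigma^{-1} f'}.
#'
#' @param f_plus,f_minus analytic mean vectors at the two conditions.
#' @param Sigma_plus,Sigma_minus analytic covariances (Sigma_minus defaults
#'   to Sigma_plus for a shared-covariance population).
#' @param dtheta stimulus separation.
#' @return object of class \code{"population_ground_truth"} with fields
#'   \code{f_plus}, \code{f_minus}, \code{f_prime}, \code{Sigma_plus},
#'   \code{Sigma_minus}, \code{Sigma_bar}, \code{dtheta}, \code{info_true}.
#' @export
population_ground_truth <- function(f_plus, f_minus, Sigma_plus,
                                    Sigma_minus = Sigma_plus, dtheta) {
  stopifnot(length(f_plus) == length(f_minus),
            nrow(Sigma_plus) == length(f_plus), dtheta > 0)
  Sigma_bar <- (Sigma_plus + Sigma_minus) / 2
  Sigma_bar <- (Sigma_bar + t(Sigma_bar)) / 2
  f_prime <- (f_plus - f_minus) / dtheta
  gt <- structure(
    list(f_plus = f_plus, f_minus = f_minus, f_prime = f_prime,
         Sigma_plus = Sigma_plus, Sigma_minus = Sigma_minus,
         Sigma_bar = Sigma_bar, dtheta = dtheta, info_true = NA_real_),
    class = "population_ground_truth")
  gt$info_true <- true_linear_info(gt)
  gt
}

#' @export
print.population_ground_truth <- function(x, ...) {
  cat(sprintf("Population ground truth: N = %d, dtheta = %g, I_true = %.6g\n",
              length(x$f_plus), x$dtheta, x$info_true))
  invisible(x)
}

#' True linear Fisher information of a known population
#'
#' \eqn{I = df^T \bar\Sigma^{-1} df / d\theta^2}: the inverse variance of the
#' locally optimal unbiased linear stimulus estimator. The coarse
#' discrimination form (finite difference of the tuning, averaged covariance)
#' reduces to \eqn{f'^T \Sigma^{-1} f'} for fine discrimination with equal
#' covariances.
#'
#' @param gt a \code{\link{population_ground_truth}}.
#' @return scalar information (stimulus-units^-2), always >= 0.
#' @export
true_linear_info <- function(gt) {
  stopifnot(inherits(gt, "population_ground_truth"))
  ev <- eigen(gt$Sigma_bar, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("Sigma_bar is not positive definite")
  as.numeric(crossprod(gt$f_prime, solve(gt$Sigma_bar, gt$f_prime)))
}

#' Locally optimal linear readout weights
#'
#' \eqn{w = \Sigma^{-1} f' / (f'^T \Sigma^{-1} f')}, normalized so that the
#' linear readout \eqn{w^T r} is an unbiased local estimator of the stimulus;
#' its variance then equals 1/I exactly.
#'
#' @param x a \code{\link{population_ground_truth}} or a
#'   \code{\link{moment_summary}} (empirical plug-in weights).
#' @return numeric weight vector of length N.
#' @export
optimal_weights <- function(x) {
  if (inherits(x, "population_ground_truth")) {
    Sigma <- x$Sigma_bar; fp <- x$f_prime
  } else {
    m <- as_moment_summary(x)
    Sigma <- m$S_pooled; fp <- m$dmu_dtheta
  }
  u <- .sym_solve(Sigma, fp, NA_integer_, length(fp))
  I <- sum(fp * u)
  if (I <= 0) stop("non-positive information; weights undefined")
  as.numeric(u / I)
}

#' Analytic crossed information
#'
#' Information that the optimal decoder of population A extracts from
#' population B:
#' \eqn{I_{AB} = (f'_B{}^T \Sigma_A^{-1} f'_A)^2 /
#'   (f'_A{}^T \Sigma_A^{-1} \Sigma_B \Sigma_A^{-1} f'_A)}.
#'
#' @param gtA,gtB ground truths for populations A and B (same N).
#' @return scalar information.
#' @export
crossed_info_true <- function(gtA, gtB) {
  stopifnot(inherits(gtA, "population_ground_truth"),
            inherits(gtB, "population_ground_truth"),
            length(gtA$f_prime) == length(gtB$f_prime))
  u <- solve(gtA$Sigma_bar, gtA$f_prime)
  as.numeric(sum(gtB$f_prime * u)^2 / (t(u) %*% gtB$Sigma_bar %*% u))
}

#' Analytic diagonal-decoder information
#'
#' Information that a factorized (correlation-blind) decoder, with weights
#' proportional to \code{diag(Sigma)^-1 f'}, extracts from the correlated
#' population: the crossed information with A the marginal-matched
#' independent population and B the population itself.
#'
#' @param gt a \code{\link{population_ground_truth}}.
#' @return scalar information.
#' @export
diag_info_true <- function(gt) {
  stopifnot(inherits(gt, "population_ground_truth"))
  d <- diag(gt$Sigma_bar)
  u <- gt$f_prime / d
  as.numeric(sum(gt$f_prime * u)^2 / (t(u) %*% gt$Sigma_bar %*% u))
}

#' Analytic shuffled information
#'
#' Information of the marginal-matched independent population:
#' \eqn{I_{shuffle} = \sum_i f_i'^2 / \sigma_i^2}.
#'
#' @param gt a \code{\link{population_ground_truth}}.
#' @return scalar information.
#' @export
shuffle_info_true <- function(gt) {
  stopifnot(inherits(gt, "population_ground_truth"))
  sum(gt$f_prime^2 / diag(gt$Sigma_bar))
}

#' Convert Fisher information to two-alternative percent correct
#'
#' For two conditions separated by \code{separation} and a population with
#' linear Fisher information \code{info}, the optimal linear readout yields
#' a Gaussian decision variable with d' = separation * sqrt(info), so the
#' ideal percent correct is \code{100 * pnorm(separation * sqrt(info) / 2)}.
#'
#' @param info linear Fisher information, >= 0.
#' @param separation stimulus separation (same units as used for info).
#' @return percent correct in [50, 100].
#' @export
info_to_percent_correct <- function(info, separation) {
  if (any(info < 0)) stop("info must be non-negative")
  100 * stats::pnorm(separation * sqrt(info) / 2)
}
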