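#' Simulate one two-condition experiment from a population model
#'
#' Generic over the generative population models: draws T trials per
#' condition and returns a \code{\link{trial_set}}. Bit-reproducible from
#' the seed.
#'
#' @param pop a population object (\code{\link{gaussian_population}},
#'   \code{\link{gabor_population}}, \code{\link{vonmises_population}}).
#' @param T trials per condition.
#' @param seed integer seed.
#' @param ... passed to methods.
#' @return a \code{\link{trial_set}}.
#' @export
simulate_experiment <- function(pop, T, seed, ...) UseMethod("simulate_experiment")

#' Analytic ground truth of a population model
#'
#' Generic returning the \code{\link{population_ground_truth}} (tuning at
#' the two conditions, covariances, true information). For the Gabor model
#' this is the rectification-ignoring approximation; for the Gaussian and
#' Von Mises models it is exact.
#'
#' @param pop a population object.
#' @param ... passed to methods.
#' @return a \code{\link{population_ground_truth}}.
#' @export
ground_truth <- function(pop, ...) UseMethod("ground_truth")

#' Gaussian population with exact ground truth
#'
#' Two-condition homoscedastic multivariate Gaussian model: responses in
#' condition +/- are N(f_plus, Sigma) / N(f_minus, Sigma). This is the model
#' under which the bias corrections are exact, and serves as the oracle for
#' unbiasedness and variance-calibration checks.
#'
#' @param f_plus,f_minus mean vectors.
#' @param Sigma covariance matrix (positive definite).
#' @param dtheta stimulus separation.
#' @return object of class \code{"gaussian_population"}.
#' @export
gaussian_population <- function(f_plus, f_minus, Sigma, dtheta) {
  stopifnot(length(f_plus) == length(f_minus),
            nrow(Sigma) == length(f_plus), dtheta > 0)
  Sigma <- (Sigma + t(Sigma)) / 2
  R <- tryCatch(chol(Sigma), error = function(e)
    stop("Sigma is not positive definite"))
  structure(list(f_plus = f_plus, f_minus = f_minus, Sigma = Sigma,
                 chol = R, dtheta = dtheta, n_neurons = length(f_plus)),
            class = "gaussian_population")
}

#' @export
simulate_experiment.gaussian_population <- function(pop, T, seed, ...) {
  N <- pop$n_neurons
  withr_seed(seed, {
    zp <- matrix(stats::rnorm(T * N), T, N) %*% pop$chol
    zm <- matrix(stats::rnorm(T * N), T, N) %*% pop$chol
    trial_set(sweep(zp, 2, pop$f_plus, "+"),
              sweep(zm, 2, pop$f_minus, "+"), pop$dtheta)
  })
}

#' @export
ground_truth.gaussian_population <- function(pop, ...) {
  population_ground_truth(pop$f_plus, pop$f_minus, pop$Sigma,
                          dtheta = pop$dtheta)
}

#' @export
print.gaussian_population <- function(x, ...) {
  cat(sprintf("Gaussian population: N = %d, dtheta = %g\n",
              x$n_neurons, x$dtheta))
  invisible(x)
}

#' Von Mises tuning with independent Poisson spiking
#'
#' Low-count population model with exact ground truth: tuning curves
#' f_i(theta) = baseline + gain * exp(kappa * (cos(theta - theta_i) - 1))
#' over evenly spaced preferred orientations, and independent Poisson
#' emission. The default baseline/gain give a population-averaged count of
#' about 0.8 spikes/neuron/trial with kappa = 2, matching the low-count
#' regime of the g = 1 Gabor simulation.
#'
#' The true information is the diagonal-Poisson closed form
#' \eqn{\sum_i f_i'^2 / \bar f_i}, with the derivative taken as the finite
#' difference over dtheta and \eqn{\bar f_i} the across-condition mean rate.
#'
#' @param N number of neurons.
#' @param baseline baseline rate (spikes/trial).
#' @param gain tuning amplitude (spikes/trial at the preferred orientation
#'   above baseline).
#' @param kappa concentration of the Von Mises tuning.
#' @param theta_plus,theta_minus condition orientations (degrees).
#' @return object of class \code{"vonmises_population"}.
#' @export
vonmises_population <- function(N = 50, baseline = 0.05, gain = 2.43,
                                kappa = 2, theta_plus = 0, theta_minus = -7) {
  stopifnot(N >= 1, baseline >= 0, gain >= 0, kappa >= 0,
            theta_plus > theta_minus, baseline + gain > 0)
  prefs <- -180 + 360 / N * (seq_len(N) - 1)
  structure(list(N = N, baseline = baseline, gain = gain, kappa = kappa,
                 prefs = prefs, theta_plus = theta_plus,
                 theta_minus = theta_minus,
                 dtheta = theta_plus - theta_minus),
            class = "vonmises_population")
}

#' Von Mises tuning curve values
#' @param pop a \code{\link{vonmises_population}}.
#' @param theta orientation (degrees).
#' @return length-N vector of mean rates (all > 0 when baseline > 0).
#' @export
vonmises_rates <- function(pop, theta) {
  stopifnot(inherits(pop, "vonmises_population"))
  d <- (theta - pop$prefs) * pi / 180
  pop$baseline + pop$gain * exp(pop$kappa * (cos(d) - 1))
}

#' @export
simulate_experiment.vonmises_population <- function(pop, T, seed, ...) {
  fp <- vonmises_rates(pop, pop$theta_plus)
  fm <- vonmises_rates(pop, pop$theta_minus)
  N <- pop$N
  withr_seed(seed, {
    rp <- matrix(stats::rpois(T * N, rep(fp, each = T)), T, N)
    rm_ <- matrix(stats::rpois(T * N, rep(fm, each = T)), T, N)
    trial_set(rp, rm_, pop$dtheta)
  })
}

#' @export
ground_truth.vonmises_population <- function(pop, ...) {
  fp <- vonmises_rates(pop, pop$theta_plus)
  fm <- vonmises_rates(pop, pop$theta_minus)
  population_ground_truth(fp, fm, diag(fp), diag(fm), dtheta = pop$dtheta)
}

#' @export
print.vonmises_population <- function(x, ...) {
  cat(sprintf("Von Mises-Poisson population: N = %d, kappa = %g, gain = %g\n",
              x$N, x$kappa, x$gain))
  invisible(x)
}

#' Reference correlated Gaussian population
#'
#' Convenience constructor of a generic correlated population for
#' calibration and recovery studies: tuning means drawn uniformly in
#' [2, 10] spikes, condition differences uniform in [-0.6, 0.6], and a
#' dense positive-definite covariance I_N + A'A with i.i.d. N(0, 0.25^2)
#' entries in A. All draws are fixed by the seed, so a given (N, seed)
#' names one concrete population.
#'
#' @param N population size.
#' @param dtheta stimulus separation (default 1).
#' @param seed integer seed.
#' @return a \code{\link{gaussian_population}}.
#' @export
example_gaussian_population <- function(N, dtheta = 1, seed = 1L) {
  withr_seed(seed, {
    f_plus <- stats::runif(N, 2, 10)
    f_minus <- f_plus + stats::runif(N, -0.6, 0.6)
    A <- matrix(stats::rnorm(N * N, sd = 0.25), N)
    gaussian_population(f_plus, f_minus, diag(N) + crossprod(A), dtheta)
  })
}
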