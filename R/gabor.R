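#' Gabor stimulus parameters
#'
#' Geometry of the input images: a Gabor patch on a P x P pixel grid,
#' corrupted by independent Gaussian pixel noise of SD \code{sigma0}.
#' Defaults follow the standard configuration of the doubly stochastic
#' V1 simulation: P = 32, envelope SD P/5, wavelength P/1.5 pixels/cycle,
#' phase 0, Michelson contrast 0.75, pixel-noise SD 0.2.
#'
#' @param P image side length in pixels.
#' @param sigma_env Gaussian envelope SD (pixels).
#' @param wavelength spatial wavelength (pixels/cycle).
#' @param phase phase offset (radians).
#' @param contrast carrier contrast.
#' @param sigma0 pixel-noise SD.
#' @return list of class \code{"gabor_stimulus_params"}.
#' @export
gabor_stimulus_params <- function(P = 32, sigma_env = P / 5,
                                  wavelength = P / 1.5, phase = 0,
                                  contrast = 0.75, sigma0 = 0.2) {
  stopifnot(P >= 4, sigma_env > 0, wavelength > 0, contrast >= 0, sigma0 >= 0)
  structure(list(P = P, sigma_env = sigma_env, wavelength = wavelength,
                 phase = phase, contrast = contrast, sigma0 = sigma0),
            class = "gabor_stimulus_params")
}

#' Gabor patch image
#'
#' \deqn{J(x, y) = c\, e^{-(x^2+y^2)/(2\sigma^2)}
#'   \cos\left(\frac{2\pi}{\lambda}(x\cos\theta + y\sin\theta) + \phi\right)}
#' on a centered integer pixel grid, x, y in {-(P-1)/2, ..., (P-1)/2}.
#'
#' @param theta orientation in degrees.
#' @param params a \code{\link{gabor_stimulus_params}}; the contrast,
#'   envelope and wavelength may be overridden for filter construction.
#' @param sigma_env,wavelength,contrast optional overrides.
#' @param normalize rescale the patch to zero mean and unit norm before
#'   applying the contrast (default FALSE, the raw analytic patch; the
#'   filter bank normalizes its own patches). The normalized convention is
#'   offered for explorations where image and filter should share a scale.
#' @return P x P numeric matrix.
#' @export
gabor_image <- function(theta, params = gabor_stimulus_params(),
                        sigma_env = params$sigma_env,
                        wavelength = params$wavelength,
                        contrast = params$contrast, normalize = FALSE) {
  P <- params$P
  g <- seq_len(P) - (P + 1) / 2
  x <- matrix(g, P, P)          # column coordinate constant per row
  y <- matrix(g, P, P, byrow = TRUE)
  th <- theta * pi / 180
  J <- exp(-(x^2 + y^2) / (2 * sigma_env^2)) *
    cos(2 * pi / wavelength * (x * cos(th) + y * sin(th)) + params$phase)
  if (normalize) {
    J <- J - mean(J)
    J <- J / sqrt(sum(J^2))
  }
  contrast * J
}

#' Build a Gabor filter-bank population
#'
#' A bank of N orientation-selective linear filters with preferred
#' orientations evenly spaced over [-180, 180) in steps of 360/N. Each
#' filter is a Gabor patch rescaled to zero mean and unit norm. Filter
#' amplitudes a_k are drawn log-normal (meanlog 0, sdlog 0.25, so the median
#' amplitude is 1); the effective tuning amplitude of neuron k is
#' g_k = gain * a_k.
#'
#' Population "B" (used for crossed-decoding scenarios) uses filters with a
#' smaller envelope (P/8) and shorter wavelength (P/3), same stimuli.
#'
#' @param N number of neurons.
#' @param gain population gain g (default 30; g = 1 gives the low-count
#'   regime of ~0.4 spikes/neuron/trial).
#' @param params stimulus parameters (shared by filters and images unless
#'   overridden).
#' @param filter_sigma,filter_wavelength filter geometry; defaults follow
#'   the stimulus.
#' @param theta_plus,theta_minus the two stimulus orientations (degrees);
#'   defaults 0 and -7 (dtheta = 7 deg fine discrimination).
#' @param amp_sdlog log-SD of the amplitude distribution.
#' @param seed integer seed for the amplitude draws.
#' @return object of class \code{"gabor_population"}: filters (N x P^2
#'   matrix, rows zero-mean unit-norm), preferred orientations, amplitudes,
#'   effective amplitudes \code{g_k}, filter Gram matrix, stimulus
#'   parameters and condition orientations.
#' @export
gabor_population <- function(N = 50, gain = 30,
                             params = gabor_stimulus_params(),
                             filter_sigma = params$sigma_env,
                             filter_wavelength = params$wavelength,
                             theta_plus = 0, theta_minus = -7,
                             amp_sdlog = 0.25, seed = 1L) {
  stopifnot(N >= 1, theta_plus > theta_minus)
  prefs <- -180 + 360 / N * (seq_len(N) - 1)
  F <- t(vapply(prefs, function(th) {
    f <- as.vector(gabor_image(th, params, sigma_env = filter_sigma,
                               wavelength = filter_wavelength, contrast = 1))
    f <- f - mean(f)
    f / sqrt(sum(f^2))
  }, numeric(params$P^2)))
  a <- withr_seed(seed, stats::rlnorm(N, meanlog = 0, sdlog = amp_sdlog))
  structure(
    list(filters = F, prefs = prefs, amplitudes = a, gain = gain,
         g_k = gain * a, gram = F %*% t(F), params = params,
         filter_sigma = filter_sigma, filter_wavelength = filter_wavelength,
         theta_plus = theta_plus, theta_minus = theta_minus,
         dtheta = theta_plus - theta_minus, seed = seed),
    class = "gabor_population")
}

#' @rdname gabor_population
#' @export
gabor_population_B <- function(N = 50, gain = 30,
                               params = gabor_stimulus_params(),
                               theta_plus = 0, theta_minus = -7,
                               amp_sdlog = 0.25, seed = 1L) {
  gabor_population(N, gain, params,
                   filter_sigma = params$P / 8,
                   filter_wavelength = params$P / 3,
                   theta_plus = theta_plus, theta_minus = theta_minus,
                   amp_sdlog = amp_sdlog, seed = seed)
}

#' @export
print.gabor_population <- function(x, ...) {
  cat(sprintf(paste0("Gabor filter-bank population: N = %d, gain = %g, ",
                     "P = %d, conditions {%g, %g} deg\n"),
              length(x$prefs), x$gain, x$params$P, x$theta_minus, x$theta_plus))
  invisible(x)
}

#' Analytic moments of the Gabor population
#'
#' Ignoring the half-rectification, the tuning and covariance are
#' \eqn{f_k(\theta) = g_k F_k \cdot J(\theta)} and
#' \eqn{\Sigma_{kl}(\theta) = \sigma_0^2 g_k g_l F_k\cdot F_l
#'   + \delta_{kl} f_k(\theta)}:
#' a low-rank pixel-noise component plus the Poisson diagonal. With phase 0
#' the filter outputs are essentially never negative, so the approximation
#' is accurate in the default high-gain regime.
#'
#' @param pop a \code{\link{gabor_population}}.
#' @param theta stimulus orientation (degrees).
#' @return list with mean vector \code{f} and covariance \code{Sigma}.
#' @export
gabor_analytic_moments <- function(pop, theta) {
  stopifnot(inherits(pop, "gabor_population"))
  j <- as.vector(gabor_image(theta, pop$params))
  f <- pop$g_k * as.numeric(pop$filters %*% j)
  Sigma <- pop$params$sigma0^2 * tcrossprod(pop$g_k) * pop$gram + diag(f)
  list(f = f, Sigma = Sigma)
}

#' @export
ground_truth.gabor_population <- function(pop, ...) {
  mp <- gabor_analytic_moments(pop, pop$theta_plus)
  mm <- gabor_analytic_moments(pop, pop$theta_minus)
  population_ground_truth(mp$f, mm$f, mp$Sigma, mm$Sigma, dtheta = pop$dtheta)
}

#' Information in the input image
#'
#' Upper bound on the information any downstream population can carry about
#' the orientation: \eqn{I_{input} = |J'|^2 / \sigma_0^2}, with J' the
#' finite-difference image derivative across the two conditions. The Gabor
#' population's information saturates below this bound as N grows
#' (information-limiting correlations).
#'
#' @param pop a \code{\link{gabor_population}}.
#' @return scalar information bound.
#' @export
gabor_input_info <- function(pop) {
  stopifnot(inherits(pop, "gabor_population"))
  jp <- gabor_image(pop$theta_plus, pop$params)
  jm <- gabor_image(pop$theta_minus, pop$params)
  sum(((jp - jm) / pop$dtheta)^2) / pop$params$sigma0^2
}

#' Simulate spike counts from the Gabor population
#'
#' Doubly stochastic generative process, per trial: draw a noisy image
#' (Gabor patch plus i.i.d. Gaussian pixel noise of SD sigma0), project it
#' on each filter, scale by the effective amplitude g_k, half-rectify, and
#' emit independent Poisson counts with that mean.
#'
#' @param pop a \code{\link{gabor_population}}.
#' @param theta stimulus orientation (degrees).
#' @param T number of trials.
#' @param seed integer seed.
#' @param chunk trials per internal block (memory control for large T).
#' @return T x N matrix of spike counts.
#' @export
simulate_gabor_trials <- function(pop, theta, T, seed, chunk = 4000L) {
  stopifnot(inherits(pop, "gabor_population"), T >= 1)
  P2 <- pop$params$P^2
  j <- as.vector(gabor_image(theta, pop$params))
  drive0 <- as.numeric(pop$filters %*% j)     # noiseless filter outputs
  N <- nrow(pop$filters)
  out <- matrix(0L, T, N)
  withr_seed(seed, {
    done <- 0L
    while (done < T) {
      nb <- min(chunk, T - done)
      noise_proj <- matrix(stats::rnorm(nb * P2, sd = pop$params$sigma0),
                           nb, P2) %*% t(pop$filters)
      rate <- pmax(sweep(noise_proj, 2, drive0, "+"), 0)
      rate <- sweep(rate, 2, pop$g_k, "*")
      out[done + seq_len(nb), ] <- stats::rpois(nb * N, rate)
      done <- done + nb
    }
  })
  out
}

#' @export
simulate_experiment.gabor_population <- function(pop, T, seed, ...) {
  trial_set(simulate_gabor_trials(pop, pop$theta_plus, T, derive_seed(seed, 1)),
            simulate_gabor_trials(pop, pop$theta_minus, T, derive_seed(seed, 2)),
            dtheta = pop$dtheta,
            labels = as.character(c(pop$theta_plus, pop$theta_minus)))
}
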