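test_that("naive and corrected estimators reproduce closed-form arithmetic", {
  # zero derivative
  expect_equal(naive_info(make_ms(rep(0, 3), diag(3), T = 10))$value, 0)
  # N = 1 scalar: dmu = 2, S = 1 -> naive 4
  expect_equal(naive_info(make_ms(2, 1, T = 7))$value, 4)
  # bias corrected, N = 1, T = 100, dtheta = 1: 4 * 196/198 - 2/100
  expect_equal(bc_info(make_ms(2, 1, T = 100), warn_noisy = FALSE)$value,
               4 * 196 / 198 - 0.02, tolerance = 1e-12)
  # shuffle, same geometry: 4 * 98/99 - 2/100
  expect_equal(bc_info_shuffle(make_ms(2, 1, T = 100))$value,
               4 * 98 / 99 - 0.02, tolerance = 1e-12)
})

test_that("correction factors and regime guards follow the trial-count bounds", {
  cf <- correction_factors(100, 50, 1)
  expect_equal(cf$c_cov, (200 - 50 - 3) / 198)
  expect_equal(cf$gamma, 2 / 100)
  expect_true(cf$c_cov > 0 && cf$c_cov < 1)

  # T <= (N+2)/2: unusable
  expect_error(bc_info(make_ms(rep(1, 20), diag(20), T = 11)), "unusable")
  # (N+2)/2 < T <= (N+5)/2: estimate returned, variance flagged divergent
  m <- make_ms(rep(1, 20), diag(20), T = 12)
  est <- suppressWarnings(bc_info(m, warn_noisy = FALSE))
  expect_true(is.finite(est$value))
  expect_true(is.na(est$analytic_variance))
  # variance formula itself refuses the divergence point T = (N+5)/2
  expect_error(bc_info_variance(1, n_trials = 12.5, n_neurons = 20, dtheta = 1),
               "diverges")
  # singular pooled covariance names the N vs 2(T-1) condition
  ts <- trial_set(matrix(rnorm(3 * 10), 3), matrix(rnorm(3 * 10), 3), 1)
  expect_error(naive_info(ts), "2\\(T-1\\)")
})

test_that("analytic variance has the stated limits", {
  # dtheta -> infinity: 2 I^2 / (2T - N - 5)
  expect_equal(bc_info_variance(3, 50, 10, 1e8), 2 * 9 / (100 - 10 - 5),
               tolerance = 1e-6)
  # I = 0: finite limit 8 N (2T-3) / ((2T-N-5) T^2 dtheta^4)
  expect_equal(bc_info_variance(0, 50, 10, 0.5),
               8 * 10 * 97 / (85 * 2500 * 0.5^4))
})

test_that("bc_info is unbiased and variance-calibrated on the Gaussian oracle", {
  pop <- example_gaussian_population(10, seed = 21)
  I <- ground_truth(pop)$info_true
  v <- mc_estimates(pop, T = 30, nrep = 3000, bc_value, seed_tag = 101)
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - I), 3.5 * se)
  expect_equal(var(v), bc_info_variance(I, 30, 10, 1), tolerance = 0.12)
})

test_that("the naive estimator's bias matches its closed form", {
  pop <- example_gaussian_population(10, seed = 22)
  I <- ground_truth(pop)$info_true
  T <- 25
  v <- mc_estimates(pop, T, nrep = 3000,
                    function(ts) naive_info(ts)$value, seed_tag = 102)
  pred <- (2 * T - 2) / (2 * T - 10 - 3) * (I + 2 * 10 / T)
  expect_lt(abs(mean(v) - pred), 4 * sd(v) / sqrt(length(v)))
})

test_that("bc_info is invariant under joint invertible linear transforms", {
  ts <- small_correlated_ts(N = 6, T = 60)
  A <- matrix(rnorm(36, sd = 0.4), 6) + diag(6)
  ts2 <- trial_set(ts$responses_plus %*% A, ts$responses_minus %*% A,
                   ts$dtheta)
  expect_equal(bc_value(ts2), bc_value(ts), tolerance = 1e-8)
  expect_equal(naive_info(ts2)$value, naive_info(ts)$value, tolerance = 1e-8)
})

test_that("shuffle estimator is unbiased for independent populations", {
  N <- 20
  pop <- withr_seed(31, {
    fp <- runif(N, 3, 8); fm <- fp + runif(N, -0.5, 0.5)
    gaussian_population(fp, fm, diag(runif(N, 0.5, 2)), dtheta = 1)
  })
  Ish <- shuffle_info_true(ground_truth(pop))
  v <- mc_estimates(pop, T = 50, nrep = 3000,
                    function(ts) bc_info_shuffle(ts)$value, seed_tag = 103)
  expect_lt(abs(mean(v) - Ish), 3.5 * sd(v) / sqrt(length(v)))
  # zero-variance neuron is reported by index
  ts <- trial_set(cbind(rnorm(10), 1), cbind(rnorm(10), 1), 1)
  expect_error(bc_info_shuffle(ts), "neuron")
})

test_that("crossed estimator matches the analytic crossed information", {
  N <- 12; T <- 40 * N
  popA <- example_gaussian_population(N, seed = 41)
  popB <- withr_seed(42, {
    fp <- popA$f_plus + runif(N, -0.1, 0.1)
    fm <- popA$f_minus + runif(N, -0.1, 0.1)
    A2 <- matrix(rnorm(N * N, sd = 0.2), N)
    gaussian_population(fp, fm, diag(N) + crossprod(A2), dtheta = 1)
  })
  IAB <- crossed_info_true(ground_truth(popA), ground_truth(popB))
  v <- vapply(1:1500, function(r) {
    a <- simulate_experiment(popA, T, seed = derive_seed(43, r))
    b <- simulate_experiment(popB, T, seed = derive_seed(44, r))
    bc_info_crossed(a, b)$value
  }, numeric(1))
  # residual ratio bias is O(1/T); at T = 40 N it is comfortably below 2.5%
  expect_lt(abs(mean(v, na.rm = TRUE) - IAB) / IAB, 0.025)
  # matching statistics: crossed truth degenerates to the plain information
  gtA <- ground_truth(popA)
  expect_equal(crossed_info_true(gtA, gtA), gtA$info_true, tolerance = 1e-10)
})

test_that("diag estimator is unbiased against the factorized-decoder truth", {
  N <- 12
  pop <- example_gaussian_population(N, seed = 51)
  Idg <- diag_info_true(ground_truth(pop))
  v <- vapply(1:1500, function(r) {
    ts <- simulate_experiment(pop, 20 * N, seed = derive_seed(52, r))
    bc_info_diag(ts, seed = derive_seed(53, r))$value
  }, numeric(1))
  expect_lt(abs(mean(v, na.rm = TRUE) - Idg) / Idg, 0.02)
})

test_that("bc, shuffle and diag agree for independent populations", {
  N <- 10
  pop <- withr_seed(61, {
    fp <- runif(N, 3, 8); fm <- fp + runif(N, -0.5, 0.5)
    gaussian_population(fp, fm, diag(runif(N, 0.5, 2)), dtheta = 1)
  })
  I <- ground_truth(pop)$info_true
  res <- vapply(1:400, function(r) {
    ts <- simulate_experiment(pop, 120, seed = derive_seed(62, r))
    c(bc_value(ts), bc_info_shuffle(ts)$value,
      bc_info_diag(ts, seed = derive_seed(63, r))$value)
  }, numeric(3))
  means <- rowMeans(res, na.rm = TRUE)
  ses <- apply(res, 1, sd, na.rm = TRUE) / sqrt(ncol(res))
  for (k in 1:3) expect_lt(abs(means[k] - I), 4 * ses[k])
})

test_that("optimal weights and the percent-correct conversion are exact", {
  # Sigma = identity: weights proportional to the tuning derivative
  gt1 <- population_ground_truth(c(2, 1), c(0, 0), diag(2), dtheta = 1)
  w1 <- optimal_weights(gt1)
  expect_equal(w1 / w1[1], c(1, 0.5))
  # N = 2 hand case: Sigma = diag(1, 4), f' = (1, 1)
  gt2 <- population_ground_truth(c(1, 1), c(0, 0),
                                 matrix(c(1, 0, 0, 4), 2), dtheta = 1)
  expect_equal(gt2$info_true, 1.25)
  w2 <- optimal_weights(gt2)
  expect_equal(w2 / w2[1], c(1, 0.25))
  # readout variance equals 1/I exactly for any positive definite Sigma
  gt3 <- ground_truth(example_gaussian_population(7, seed = 71))
  w3 <- optimal_weights(gt3)
  expect_equal(as.numeric(t(w3) %*% gt3$Sigma_bar %*% w3),
               1 / gt3$info_true, tolerance = 1e-10)
  # unbiased readout: w' f' = 1
  expect_equal(sum(w3 * gt3$f_prime), 1, tolerance = 1e-10)

  expect_equal(info_to_percent_correct(0, 7), 50)
  expect_equal(info_to_percent_correct(1e8, 7), 100)
  expect_error(info_to_percent_correct(-1, 7), "non-negative")

  # Monte-Carlo decoding agrees with the Gaussian conversion formula
  pop <- example_gaussian_population(5, dtheta = 2, seed = 72)
  gt <- ground_truth(pop)
  w <- optimal_weights(gt)
  thr <- sum(w * (gt$f_plus + gt$f_minus)) / 2
  ts <- simulate_experiment(pop, 4000, seed = 73)
  pc <- 100 * mean(c(ts$responses_plus %*% w > thr,
                     ts$responses_minus %*% w < thr))
  pred <- info_to_percent_correct(gt$info_true, pop$dtheta)
  expect_lt(abs(pc - pred), 100 * 3 * sqrt(0.25 / 8000))
})

test_that("negative noisy estimates are returned with a warning, not clipped", {
  # nearly zero information, tiny T: bias correction can push below zero
  pop <- gaussian_population(rep(5, 8), rep(5, 8) + 1e-4, diag(8), dtheta = 1)
  vals <- suppressWarnings(
    mc_estimates(pop, T = 12, nrep = 200, bc_value, seed_tag = 81))
  expect_true(any(vals < 0))
  m <- summarize_trials(simulate_experiment(pop, 12, seed = 1))
  expect_warning(bc_info(m), "magnitude")
})
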