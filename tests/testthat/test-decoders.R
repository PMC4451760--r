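test_that("split_trials partitions per condition with largest-remainder sizes", {
  ts <- small_correlated_ts(N = 3, T = 300)
  parts <- split_trials(ts, split_config(seed = 4))
  expect_equal(vapply(parts, function(p) p$n_trials, numeric(1)),
               c(train = 100, test = 100, validation = 100))

  ts2 <- small_correlated_ts(N = 3, T = 100)
  parts2 <- split_trials(ts2, split_config(c(0.34, 0.33, 0.33), seed = 4))
  expect_equal(unname(vapply(parts2, function(p) p$n_trials, numeric(1))),
               c(34, 33, 33))

  # disjoint and exhaustive: the union of rows equals the original multiset
  all_plus <- do.call(rbind, lapply(parts, function(p) p$responses_plus))
  expect_equal(all_plus[order(all_plus[, 1]), ],
               ts$responses_plus[order(ts$responses_plus[, 1]), ])

  # determinism
  parts3 <- split_trials(ts, split_config(seed = 4))
  expect_identical(parts$train$responses_plus, parts3$train$responses_plus)
  expect_error(split_trials(small_correlated_ts(T = 4), split_config(seed = 1)),
               "too few")
})

test_that("shuffle_trials preserves marginals and destroys correlations", {
  ts <- small_correlated_ts(N = 4, T = 50)
  sh <- shuffle_trials(ts, seed = 9)
  for (j in 1:4) {
    expect_equal(sort(sh$responses_plus[, j]), sort(ts$responses_plus[, j]))
    expect_equal(sort(sh$responses_minus[, j]), sort(ts$responses_minus[, j]))
  }
  # N = 1: estimators are permutation invariant
  ts1 <- trial_set(matrix(rnorm(30, 5)), matrix(rnorm(30, 4)), 1)
  expect_equal(bc_value(shuffle_trials(ts1, 3)), bc_value(ts1))

  # strongly correlated pair: shuffling wipes the correlation
  Sig <- matrix(c(1, 0.95, 0.95, 1), 2)
  pop <- gaussian_population(c(5, 5), c(4.5, 4.5), Sig, 1)
  big <- simulate_experiment(pop, 1e4, seed = 10)
  shb <- shuffle_trials(big, seed = 11)
  expect_gt(cor(big$responses_plus)[1, 2], 0.9)
  expect_lt(abs(cor(shb$responses_plus)[1, 2]), 0.05)
})

test_that("gradient descent converges to least squares on easy data", {
  # N = 1, strong signal: weight approaches the least-squares slope
  set.seed(2)
  rp <- matrix(rnorm(60, 10, 0.5)); rm_ <- matrix(rnorm(60, 2, 0.5))
  tr <- trial_set(rp[1:30, , drop = FALSE], rm_[1:30, , drop = FALSE], 2)
  te <- trial_set(rp[31:60, , drop = FALSE], rm_[31:60, , drop = FALSE], 2)
  fit <- train_early_stopping(tr, te, seed = 1, max_iter = 5000)
  X <- c(rp[1:30], rm_[1:30]) - mean(c(rp[1:30], rm_[1:30]))
  y <- rep(c(1, -1), each = 30)
  wls <- sum(X * y) / sum(X^2)
  expect_equal(fit$weights, wls, tolerance = 0.05, ignore_attr = TRUE)

  # a wildly excessive learning rate is reported as such
  expect_error(train_early_stopping(tr, te, lr = 1e6, seed = 1),
               "learning rate")
})

test_that("with abundant data the decoder recovers the optimal weights", {
  N <- 5
  pop <- example_gaussian_population(N, seed = 12)
  ts <- simulate_experiment(pop, 500 * N, seed = 13)
  parts <- split_trials(ts, split_config(seed = 14))
  fit <- train_early_stopping(parts$train, parts$test, seed = 15)
  w_opt <- optimal_weights(ground_truth(pop))
  cosine <- sum(fit$weights * w_opt) /
    sqrt(sum(fit$weights^2) * sum(w_opt^2))
  expect_gt(cosine, 0.95)
})

test_that("decoder_info is scale- and shift-invariant and exact for optimal w", {
  ts <- small_correlated_ts(N = 5, T = 90)
  w <- rnorm(5)
  i1 <- decoder_info(w, ts)$value
  expect_equal(decoder_info(3.7 * w, ts)$value, i1, tolerance = 1e-12)
  shifted <- trial_set(ts$responses_plus + 2, ts$responses_minus + 2,
                       ts$dtheta)
  expect_equal(decoder_info(w, shifted)$value, i1, tolerance = 1e-9)

  # on analytic moments the optimal weights recover I exactly:
  # the crossed information of a population with itself is its information
  gt <- ground_truth(example_gaussian_population(6, seed = 16))
  expect_equal(crossed_info_true(gt, gt), gt$info_true, tolerance = 1e-10)
})

test_that("the pipeline is reproducible and training exceeds validation", {
  pop <- example_gaussian_population(12, seed = 17)
  ts <- simulate_experiment(pop, 60, seed = 18)
  a <- decoder_pipeline(ts, seed = 7)
  b <- decoder_pipeline(ts, seed = 7)
  expect_identical(a$validation$value, b$validation$value)
  expect_identical(a$fit$weights, b$fit$weights)

  # overfitting direction: training-set information above validation-set
  res <- vapply(1:25, function(r) {
    tsx <- simulate_experiment(pop, 36, seed = derive_seed(19, r))
    dp <- decoder_pipeline(tsx, seed = derive_seed(20, r))
    c(dp$training$value, dp$validation$value)
  }, numeric(2))
  expect_gt(mean(res[1, ] > res[2, ]), 0.7)
  expect_gt(mean(res[1, ]), mean(res[2, ]))
})

test_that("decoder validation and bc_info agree asymptotically", {
  N <- 5
  pop <- example_gaussian_population(N, seed = 23)
  res <- vapply(1:150, function(r) {
    ts <- simulate_experiment(pop, 100 * N, seed = derive_seed(24, r))
    dp <- decoder_pipeline(ts, seed = derive_seed(25, r))
    c(dp$validation$value, bc_value(ts))
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - mean(res[2, ])) / mean(res[2, ]), 0.02)
})

test_that("decoder modes use the advertised data routing", {
  pop <- example_gaussian_population(8, seed = 26)
  ts <- simulate_experiment(pop, 90, seed = 27)
  tsb <- simulate_experiment(pop, 90, seed = 28)
  for (mode in c("plain", "shuffle", "diag")) {
    dp <- decoder_pipeline(ts, mode = mode, seed = 5)
    expect_s3_class(dp$validation, "info_estimate")
    expect_identical(dp$validation$method, "decoder_validation")
  }
  dp <- decoder_pipeline(ts, mode = "crossed", data_b = tsb, seed = 5)
  # crossed mode validates on the full second dataset
  expect_equal(dp$validation$n_trials, tsb$n_trials)
  expect_error(decoder_pipeline(ts, mode = "crossed", seed = 5))
})
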