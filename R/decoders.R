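#' Train/test/validation split configuration
#'
#' @param fractions positive length-3 numeric (training, test, validation)
#'   summing to 1; default equal thirds.
#' @param seed integer seed for the random partition.
#' @return object of class \code{"split_config"}.
#' @export
split_config <- function(fractions = c(train = 1/3, test = 1/3, validation = 1/3),
                         seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "split_config")
}

# largest-remainder apportionment of T trials into length(frac) parts
.apportion <- function(T, frac) {
  base <- floor(T * frac)
  rem <- T - sum(base)
  if (rem > 0) {
    extra <- order(T * frac - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a trial set into training, test and validation sets
#'
#' Per-condition stratified random partition: within each condition the
#' trials are randomly permuted and dealt into three disjoint, exhaustive
#' subsets whose sizes follow the configured fractions (largest-remainder
#' rounding). Reproducible from the configuration seed.
#'
#' @param data a \code{\link{trial_set}}.
#' @param cfg a \code{\link{split_config}}.
#' @return named list of three \code{trial_set}s: \code{train}, \code{test},
#'   \code{validation}.
#' @export
split_trials <- function(data, cfg = split_config()) {
  stopifnot(inherits(data, "trial_set"), inherits(cfg, "split_config"))
  T <- data$n_trials
  sizes <- .apportion(T, cfg$fractions)
  if (any(sizes < 2))
    stop("too few trials: every split needs >= 2 trials per condition")
  idx <- withr_seed(cfg$seed, list(sample.int(T), sample.int(T)))
  bounds <- c(0, cumsum(sizes))
  out <- lapply(1:3, function(k) {
    sel <- (bounds[k] + 1):bounds[k + 1]
    trial_set(data$responses_plus[idx[[1]][sel], , drop = FALSE],
              data$responses_minus[idx[[2]][sel], , drop = FALSE],
              data$dtheta, labels = data$labels)
  })
  names(out) <- c("train", "test", "validation")
  out
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Shuffle responses across trials, per neuron and condition
#'
#' Destroys noise correlations while preserving every neuron's marginal
#' response histogram exactly: within each condition, each neuron's column
#' is independently permuted across trials.
#'
#' @param data a \code{\link{trial_set}}.
#' @param seed integer seed.
#' @return a shuffled \code{\link{trial_set}}.
#' @export
shuffle_trials <- function(data, seed) {
  stopifnot(inherits(data, "trial_set"))
  T <- data$n_trials; N <- data$n_neurons
  withr_seed(seed, {
    sp <- vapply(seq_len(N), function(j) data$responses_plus[sample.int(T), j],
                 numeric(T))
    sm <- vapply(seq_len(N), function(j) data$responses_minus[sample.int(T), j],
                 numeric(T))
    trial_set(sp, sm, data$dtheta, labels = data$labels)
  })
}

#' Train a linear decoder by gradient descent with early stopping
#'
#' Finds readout weights w minimizing the squared stimulus regression error
#' E = sum_t (theta_t - <theta> - w'(r_t - <r>))^2 by full-batch gradient
#' descent on the training set, monitoring the error on the held-out test
#' set. Training stops when the smoothed test error (moving window) rises
#' above its running minimum; the weights at the test-error minimum are
#' returned. Weights are initialized from a small random draw.
#'
#' @param train,test \code{\link{trial_set}}s for training and test.
#' @param lr learning rate; default 1/(2 L) with L the largest eigenvalue of
#'   the centered training second-moment matrix (guaranteed-stable step).
#' @param seed integer seed for the weight initialization.
#' @param max_iter iteration cap (default 1e5); reaching it is recorded in
#'   the stopping reason.
#' @param smooth_window moving-average window (iterations) for the test
#'   error used by the stopping rule; default 5.
#' @param init_sd weight initialization SD as a fraction of the inverse
#'   response scale; default 1e-3.
#' @return object of class \code{"decoder_fit"}: weights, response centering
#'   vector, learning rate, iteration count, training/test error
#'   trajectories, stopping reason, and the trial geometry.
#' @export
train_early_stopping <- function(train, test, lr = NULL, seed = 1L,
                                 max_iter = 1e5L, smooth_window = 5L,
                                 init_sd = 1e-3) {
  stopifnot(inherits(train, "trial_set"), inherits(test, "trial_set"),
            train$n_neurons == test$n_neurons)
  dth <- train$dtheta
  Xtr <- rbind(train$responses_plus, train$responses_minus)
  ytr <- rep(c(dth / 2, -dth / 2), each = train$n_trials)
  center <- colMeans(Xtr)
  Xtr <- sweep(Xtr, 2, center)
  Xte <- sweep(rbind(test$responses_plus, test$responses_minus), 2, center)
  yte <- rep(c(dth / 2, -dth / 2), each = test$n_trials)
  ntr <- nrow(Xtr); nte <- nrow(Xte)
  M <- crossprod(Xtr) / ntr
  if (is.null(lr)) {
    L <- max(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    lr <- 1 / (2 * L)
  }
  rscale <- sqrt(mean(Xtr^2))
  w <- withr_seed(seed, stats::rnorm(ncol(Xtr), 0,
                                     init_sd * dth / max(rscale, 1e-12)))
  b <- colMeans(Xtr * ytr)              # t(Xtr) %*% ytr / ntr
  e_tr <- e_te <- numeric(max_iter)
  best_err <- Inf; best_w <- w; best_iter <- 0L
  smooth_min <- Inf
  reason <- "max_iter"
  n_diverge <- 0L
  for (it in seq_len(max_iter)) {
    res_tr <- ytr - as.numeric(Xtr %*% w)
    e_tr[it] <- mean(res_tr^2)
    e_te[it] <- mean((yte - as.numeric(Xte %*% w))^2)
    if (e_te[it] < best_err) {
      best_err <- e_te[it]; best_w <- w; best_iter <- it
    }
    # full-batch descent on a quadratic has non-increasing training error;
    # persistent or explosive growth can only mean an unstable learning rate
    if (!is.finite(e_tr[it]) || e_tr[it] > 100 * e_tr[1])
      stop("training error diverged: reduce the learning rate")
    if (it > 1 && e_tr[it] > e_tr[it - 1]) {
      n_diverge <- n_diverge + 1L
      if (n_diverge >= 25L)
        stop("training error increases persistently: reduce the learning rate")
    } else n_diverge <- 0L
    if (it >= smooth_window) {
      sm <- mean(e_te[(it - smooth_window + 1):it])
      if (sm < smooth_min) smooth_min <- sm
      else if (sm > smooth_min) { reason <- "test_error_increase"; break }
    }
    # gradient of mean squared error: -2 (b - M w); step = lr * (b - M w)
    w <- w + 2 * lr * (b - as.numeric(M %*% w))
  }
  it <- min(it, max_iter)
  structure(
    list(weights = best_w, center = center, lr = lr, iterations = it,
         best_iteration = best_iter,
         train_error = e_tr[seq_len(it)], test_error = e_te[seq_len(it)],
         stopping_reason = reason,
         n_neurons = train$n_neurons, dtheta = dth),
    class = "decoder_fit")
}

#' @export
print.decoder_fit <- function(x, ...) {
  cat(sprintf("Linear decoder fit: N = %d, %d iterations (best at %d), stopped on %s\n",
              x$n_neurons, x$iterations, x$best_iteration, x$stopping_reason))
  invisible(x)
}

#' Decoder-based information estimate on an evaluation set
#'
#' Estimates the information extracted by fixed readout weights w from fresh
#' data:
#' \deqn{\hat I = \frac{[w^T(\langle r^+\rangle - \langle r^-\rangle)/d\theta]^2}
#'   {w^T \bar S w}}
#' with \eqn{\bar S} the average of the two per-condition sample covariances
#' of the evaluation set. The numerator normalization makes the estimate
#' invariant to any rescaling of w (it corrects for decoder miscalibration).
#'
#' @param fit a \code{\link{decoder_fit}} (or bare numeric weight vector).
#' @param eval_set \code{\link{trial_set}} on which to evaluate.
#' @param method tag recording the provenance of the evaluation set:
#'   "decoder_validation" (default) or "decoder_training".
#' @return an \code{\link{info_estimate}}.
#' @export
decoder_info <- function(fit, eval_set, method = "decoder_validation") {
  w <- if (inherits(fit, "decoder_fit")) fit$weights else as.numeric(fit)
  m <- summarize_trials(eval_set)
  stopifnot(length(w) == m$n_neurons)
  den <- as.numeric(t(w) %*% m$S_pooled %*% w)
  if (den <= 0) stop("degenerate readout: w' S w <= 0 on the evaluation set")
  val <- sum(w * m$dmu_dtheta)^2 / den
  info_estimate(val, method, m$n_trials, m$n_neurons, m$dtheta)
}

#' Full cross-validated decoder pipeline
#'
#' Splits the data, trains the early-stopping decoder, and returns the
#' information estimated on the training and validation sets. Modes:
#' \describe{
#'   \item{plain}{train/test/validate on the original data.}
#'   \item{shuffle}{train/test/validate on a trial-shuffled copy
#'     (decoder-based shuffled information).}
#'   \item{diag}{train and early-stop on shuffled data, validate on the
#'     original data (decoder-based diagonal information).}
#'   \item{crossed}{train and early-stop on dataset A, validate on dataset B
#'     (requires \code{data_b}).}
#' }
#'
#' @param data a \code{\link{trial_set}}.
#' @param mode one of "plain", "shuffle", "diag", "crossed".
#' @param data_b second \code{\link{trial_set}} for mode "crossed".
#' @param fractions split fractions (see \code{\link{split_config}}).
#' @param lr,max_iter passed to \code{\link{train_early_stopping}}.
#' @param seed integer master seed (splits, shuffles, initialization).
#' @return list with \code{training} and \code{validation}
#'   \code{\link{info_estimate}}s and the \code{fit}.
#' @export
decoder_pipeline <- function(data, mode = c("plain", "shuffle", "diag", "crossed"),
                             data_b = NULL, fractions = c(1, 1, 1) / 3,
                             lr = NULL, max_iter = 1e5L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "trial_set"))
  if (mode == "shuffle")
    data <- shuffle_trials(data, derive_seed(seed, 7))
  cfg <- split_config(fractions, seed = derive_seed(seed, 11))
  parts <- split_trials(data, cfg)
  train <- parts$train; test <- parts$test; val <- parts$validation
  if (mode == "diag") {
    train <- shuffle_trials(train, derive_seed(seed, 13))
    test <- shuffle_trials(test, derive_seed(seed, 17))
  }
  if (mode == "crossed") {
    stopifnot(inherits(data_b, "trial_set"))
    val <- data_b
  }
  fit <- train_early_stopping(train, test, lr = lr,
                              seed = derive_seed(seed, 19),
                              max_iter = max_iter)
  list(training = decoder_info(fit, train, method = "decoder_training"),
       validation = decoder_info(fit, val, method = "decoder_validation"),
       fit = fit)
}
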