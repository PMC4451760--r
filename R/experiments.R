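#' Configure an estimator-comparison sweep
#'
#' Describes a Monte-Carlo sweep over trial counts: which generative
#' population to simulate, which estimators to apply, how many replicate
#' experiments per trial count, and the master seed from which every
#' replicate seed is derived (so results are reproducible under reordering
#' or parallel scheduling of replicates).
#'
#' @param population a population model understood by
#'   \code{\link{simulate_experiment}}.
#' @param T_values integer vector of trials-per-condition to sweep.
#' @param n_rep replicate experiments per T (default 200).
#' @param estimators character subset of c("naive", "bc", "shuffle", "diag",
#'   "crossed", "decoder").
#' @param population_b second population, required when "crossed" is
#'   requested.
#' @param decoder list of decoder settings (\code{fractions}, \code{lr},
#'   \code{max_iter}) passed to \code{\link{decoder_pipeline}}.
#' @param n_rep_decoder replicate count for the decoder (defaults to
#'   \code{n_rep}; the decoder is the costly component and may use fewer).
#' @param ground_truth_values optional named numeric vector overriding the
#'   analytic ground truth (e.g. an operational large-T value for low-count
#'   models); names among "bc", "naive", "shuffle", "diag", "crossed",
#'   "decoder".
#' @param master_seed integer master seed.
#' @return object of class \code{"sweep_config"}.
#' @export
sweep_config <- function(population, T_values, n_rep = 200,
                         estimators = c("bc", "decoder"),
                         population_b = NULL, decoder = list(),
                         n_rep_decoder = n_rep,
                         ground_truth_values = NULL,
                         master_seed = 1L) {
  estimators <- match.arg(estimators,
                          c("naive", "bc", "shuffle", "diag", "crossed",
                            "decoder"), several.ok = TRUE)
  if ("crossed" %in% estimators && is.null(population_b))
    stop("estimator 'crossed' requires population_b")
  stopifnot(length(T_values) >= 1, all(T_values >= 2), n_rep >= 1)
  structure(list(population = population, T_values = as.integer(T_values),
                 n_rep = as.integer(n_rep), estimators = estimators,
                 population_b = population_b, decoder = decoder,
                 n_rep_decoder = as.integer(n_rep_decoder),
                 ground_truth_values = ground_truth_values,
                 master_seed = as.integer(master_seed)),
            class = "sweep_config")
}

# ground truth per estimator label (analytic unless overridden)
.sweep_truths <- function(cfg) {
  gt <- ground_truth(cfg$population)
  truths <- c(bc = gt$info_true, naive = gt$info_true,
              decoder = gt$info_true,
              shuffle = shuffle_info_true(gt), diag = diag_info_true(gt),
              crossed = if (!is.null(cfg$population_b))
                crossed_info_true(gt, ground_truth(cfg$population_b))
              else NA_real_)
  prov <- stats::setNames(rep("analytic", length(truths)), names(truths))
  if (!is.null(cfg$ground_truth_values)) {
    ov <- cfg$ground_truth_values
    truths[names(ov)] <- ov
    prov[names(ov)] <- "operational"
  }
  list(truths = truths, provenance = prov)
}

.apply_estimators <- function(cfg, ts, ts_b, seed, with_decoder) {
  out <- c()
  m <- summarize_trials(ts)
  for (est in cfg$estimators) {
    val <- switch(est,
      naive = naive_info(m)$value,
      bc = bc_info(m, warn_noisy = FALSE)$value,
      shuffle = bc_info_shuffle(m)$value,
      diag = bc_info_diag(ts, seed = derive_seed(seed, 101))$value,
      crossed = bc_info_crossed(m, summarize_trials(ts_b))$value,
      decoder = if (with_decoder) {
        dp <- do.call(decoder_pipeline,
                      c(list(data = ts, seed = derive_seed(seed, 103)),
                        cfg$decoder))
        dp$validation$value
      } else NA_real_)
    out[est] <- val
  }
  out
}

#' Run an estimator-comparison sweep
#'
#' For each trial count and replicate: simulate a fresh experiment from the
#' configured population, apply every configured estimator, and record the
#' estimate. Aggregates mean, SD, mean squared error against the ground
#' truth, and the relative error sqrt(MSE)/truth. Replicate seeds are
#' derived deterministically from the master seed, T and the replicate
#' index. Estimator failures in invalid regimes are recorded as NA for that
#' cell, not fatal.
#'
#' @param cfg a \code{\link{sweep_config}}.
#' @return object of class \code{"sweep_result"}: a list with
#'   \code{table} (data.frame: estimator, T, mean, sd, mse, rel_err, n),
#'   \code{estimates} (nested list of raw estimates),
#'   \code{ground_truth} and \code{gt_provenance} (named vectors),
#'   \code{master_seed}.
#' @export
run_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  tr <- .sweep_truths(cfg)
  rows <- list(); estimates <- list()
  for (T in cfg$T_values) {
    nrep <- max(cfg$n_rep,
                if ("decoder" %in% cfg$estimators) cfg$n_rep_decoder else 0L)
    reps <- vapply(seq_len(nrep), function(r) {
      seed <- derive_seed(cfg$master_seed, T, r)
      ts <- simulate_experiment(cfg$population, T, seed)
      ts_b <- if (!is.null(cfg$population_b))
        simulate_experiment(cfg$population_b, T, derive_seed(seed, 5)) else NULL
      with_dec <- r <= cfg$n_rep_decoder
      tryCatch(.apply_estimators(cfg, ts, ts_b, seed, with_dec),
               error = function(e)
                 stats::setNames(rep(NA_real_, length(cfg$estimators)),
                                 cfg$estimators))
    }, stats::setNames(numeric(length(cfg$estimators)), cfg$estimators))
    reps <- matrix(reps, nrow = length(cfg$estimators),
                   dimnames = list(cfg$estimators, NULL))
    estimates[[as.character(T)]] <- reps
    for (est in cfg$estimators) {
      v <- reps[est, ]
      n_used <- if (est == "decoder") min(cfg$n_rep_decoder, nrep) else cfg$n_rep
      v <- v[seq_len(n_used)]
      v <- v[!is.na(v)]
      truth <- tr$truths[[est]]
      mse <- mean((v - truth)^2)
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = est, T = T, mean = mean(v),
        sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
        mse = mse, rel_err = sqrt(mse) / truth, n = length(v))
    }
  }
  structure(list(table = do.call(rbind, rows), estimates = estimates,
                 ground_truth = tr$truths[cfg$estimators],
                 gt_provenance = tr$provenance[cfg$estimators],
                 master_seed = cfg$master_seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, digits = 4, ...) {
  cat("Estimator comparison sweep (master seed", x$master_seed, ")\n")
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Bootstrap uncertainty band for a set of estimates
#'
#' Resamples the replicate estimates with replacement and returns the mean
#' plus/minus one bootstrap standard deviation. By default the band reflects
#' the spread of the estimate distribution (matching the visual spread of
#' replicate experiments); \code{type = "mean"} gives the tighter band for
#' the mean itself.
#'
#' @param estimates numeric vector (>= 2 values).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param type "distribution" (default) or "mean".
#' @return named numeric: \code{mean}, \code{lower}, \code{upper}.
#' @export
bootstrap_bands <- function(estimates, n_boot = 1000, seed = 1L,
                            type = c("distribution", "mean")) {
  type <- match.arg(type)
  estimates <- estimates[!is.na(estimates)]
  stopifnot(length(estimates) >= 2)
  stat <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      s <- sample(estimates, replace = TRUE)
      if (type == "mean") mean(s) else stats::sd(s)
    }, numeric(1))
  })
  m <- mean(estimates)
  hw <- if (type == "mean") stats::sd(stat) else mean(stat)
  c(mean = m, lower = m - hw, upper = m + hw)
}

#' Subsample trials without replacement
#'
#' The learning-curve protocol for a fixed recorded dataset: draws
#' \code{n_rep} independent per-condition subsamples of \code{T_sub} trials
#' (without replacement within each subsample) from the full trial set.
#'
#' @param data a \code{\link{trial_set}}.
#' @param T_sub trials per condition in each subsample (<= T).
#' @param n_rep number of subsamples (default 100).
#' @param seed integer seed.
#' @return list of \code{n_rep} \code{\link{trial_set}}s.
#' @export
subsample_trials <- function(data, T_sub, n_rep = 100, seed = 1L) {
  stopifnot(inherits(data, "trial_set"))
  if (T_sub > data$n_trials)
    stop("T_sub exceeds the number of available trials")
  lapply(seq_len(n_rep), function(r) {
    withr_seed(derive_seed(seed, 301, r), {
      ip <- sample.int(data$n_trials, T_sub)
      im <- sample.int(data$n_trials, T_sub)
      trial_set(data$responses_plus[ip, , drop = FALSE],
                data$responses_minus[im, , drop = FALSE],
                data$dtheta, labels = data$labels)
    })
  })
}

#' Write a sweep result to JSON and CSV
#'
#' The CSV holds the seven-column aggregate table (estimator, T, mean, sd,
#' mse, rel_err, n); the JSON additionally carries the ground truth values,
#' their provenance, the master seed and the package version.
#'
#' @param result a \code{\link{run_sweep}} result.
#' @param path_prefix output path without extension; writes
#'   \code{<prefix>.json} and \code{<prefix>.csv}.
#' @return invisibly, the two paths.
#' @export
write_sweep_report <- function(result, path_prefix) {
  stopifnot(inherits(result, "sweep_result"))
  csv <- paste0(path_prefix, ".csv")
  json <- paste0(path_prefix, ".json")
  utils::write.csv(result$table, csv, row.names = FALSE)
  jsonlite::write_json(
    list(table = result$table,
         ground_truth = as.list(result$ground_truth),
         gt_provenance = as.list(result$gt_provenance),
         master_seed = result$master_seed,
         package_version = as.character(utils::packageVersion("fisherbc"))),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(json = json, csv = csv))
}

#' Read back a sweep report written by \code{\link{write_sweep_report}}
#'
#' @param path_prefix path prefix used when writing.
#' @return list with \code{table} (data.frame), \code{ground_truth},
#'   \code{gt_provenance}, \code{master_seed}.
#' @export
read_sweep_report <- function(path_prefix) {
  x <- jsonlite::read_json(paste0(path_prefix, ".json"), simplifyVector = TRUE)
  x$table <- as.data.frame(x$table)
  x$ground_truth <- unlist(x$ground_truth)
  x$gt_provenance <- unlist(x$gt_provenance)
  x
}
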