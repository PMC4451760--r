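#' Two-condition trial set
#'
#' Container for the responses of a population of \code{N} neurons recorded
#' over \code{T} trials in each of two stimulus conditions separated by
#' \code{dtheta}. This is the common currency of all estimators: spike counts
#' (or rates) are stored as trial-by-neuron matrices, one per condition.
#'
#' @param responses_plus numeric T x N matrix of responses to the first
#'   condition (theta-plus).
#' @param responses_minus numeric T x N matrix of responses to the second
#'   condition (theta-minus); same dimensions as \code{responses_plus}.
#' @param dtheta positive scalar, the full stimulus separation
#'   theta-plus minus theta-minus, in stimulus units (e.g. degrees).
#' @param labels optional length-2 character vector naming the conditions.
#'
#' @return An object of class \code{"trial_set"}: a list with elements
#'   \code{responses_plus}, \code{responses_minus}, \code{dtheta},
#'   \code{n_trials}, \code{n_neurons}, \code{labels}.
#' @examples
#' ts <- trial_set(matrix(rpois(20, 5), 10), matrix(rpois(20, 4), 10), dtheta = 7)
#' summarize_trials(ts)
#' @export
trial_set <- function(responses_plus, responses_minus, dtheta, labels = NULL) {
  responses_plus <- as.matrix(responses_plus)
  responses_minus <- as.matrix(responses_minus)
  if (!is.numeric(responses_plus) || !is.numeric(responses_minus))
    stop("responses must be numeric matrices")
  if (!all(dim(responses_plus) == dim(responses_minus)))
    stop("the two response matrices must have identical dimensions")
  if (nrow(responses_plus) < 2L)
    stop("at least 2 trials per condition are required")
  if (!all(is.finite(responses_plus)) || !all(is.finite(responses_minus)))
    stop("responses contain non-finite entries")
  if (!is.numeric(dtheta) || length(dtheta) != 1L || !is.finite(dtheta) ||
      dtheta <= 0)
    stop("dtheta must be a positive finite scalar")
  structure(
    list(responses_plus = responses_plus,
         responses_minus = responses_minus,
         dtheta = as.numeric(dtheta),
         n_trials = nrow(responses_plus),
         n_neurons = ncol(responses_plus),
         labels = labels),
    class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Two-condition trial set: %d neurons, %d trials/condition, dtheta = %g\n",
              x$n_neurons, x$n_trials, x$dtheta))
  invisible(x)
}

#' Empirical moments of a two-condition trial set
#'
#' Computes the per-condition means and unbiased sample covariances, the
#' pooled covariance \code{(S_plus + S_minus)/2}, and the finite-difference
#' tuning derivative \code{(mu_plus - mu_minus)/dtheta}. These sufficient
#' statistics are the inputs of all direct information estimators.
#'
#' @param data a \code{\link{trial_set}}.
#' @return An object of class \code{"moment_summary"}: a list with
#'   \code{mu_plus}, \code{mu_minus}, \code{S_plus}, \code{S_minus},
#'   \code{S_pooled}, \code{dmu_dtheta}, \code{n_trials}, \code{n_neurons},
#'   \code{dtheta}.
#' @export
summarize_trials <- function(data) {
  stopifnot(inherits(data, "trial_set"))
  rp <- data$responses_plus
  rm_ <- data$responses_minus
  S_plus <- stats::cov(rp)        # 1/(T-1) unbiased form
  S_minus <- stats::cov(rm_)
  mu_plus <- colMeans(rp)
  mu_minus <- colMeans(rm_)
  S_pooled <- (S_plus + S_minus) / 2
  S_pooled <- (S_pooled + t(S_pooled)) / 2
  structure(
    list(mu_plus = mu_plus,
         mu_minus = mu_minus,
         S_plus = S_plus,
         S_minus = S_minus,
         S_pooled = S_pooled,
         dmu_dtheta = (mu_plus - mu_minus) / data$dtheta,
         n_trials = data$n_trials,
         n_neurons = data$n_neurons,
         dtheta = data$dtheta),
    class = "moment_summary")
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("Moment summary: %d neurons, %d trials/condition, dtheta = %g\n",
              x$n_neurons, x$n_trials, x$dtheta))
  invisible(x)
}

#' Read a two-condition trial set from CSV files
#'
#' Each file holds one condition: one row per trial, one column per neuron.
#'
#' @param file_plus,file_minus paths to the CSV files for the two conditions.
#' @param dtheta the stimulus separation (not stored in the CSVs).
#' @param header logical, whether the files carry a header row.
#' @return a \code{\link{trial_set}}.
#' @export
read_trial_set <- function(file_plus, file_minus, dtheta, header = TRUE) {
  rp <- as.matrix(utils::read.csv(file_plus, header = header))
  rm_ <- as.matrix(utils::read.csv(file_minus, header = header))
  if (!all(dim(rp) == dim(rm_)))
    stop("condition files have mismatched dimensions: ",
         paste(dim(rp), collapse = "x"), " vs ", paste(dim(rm_), collapse = "x"))
  trial_set(rp, rm_, dtheta)
}

#' Write a two-condition trial set to CSV files
#'
#' @param data a \code{\link{trial_set}}.
#' @param file_plus,file_minus output paths, one per condition.
#' @return invisibly, the two paths.
#' @export
write_trial_set <- function(data, file_plus, file_minus) {
  stopifnot(inherits(data, "trial_set"))
  utils::write.csv(as.data.frame(data$responses_plus), file_plus, row.names = FALSE)
  utils::write.csv(as.data.frame(data$responses_minus), file_minus, row.names = FALSE)
  invisible(c(file_plus, file_minus))
}
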