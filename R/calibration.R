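#' Accuracy versus detection criterion
#'
#' Evaluates the strict-greater detection rule at every criterion on the
#' grid 0.00, 0.01, ..., 1.00 and records the resulting accuracy (fraction
#' of trials whose decision matches the ground truth). At the extreme
#' criteria of a balanced set the accuracy is the 0.5 chance level.
#'
#' @param scores Representative scores, one per trial.
#' @param truth Logical ground-truth tumor presence, same length.
#' @param criteria Criterion grid (default 101 points, 0.01 steps).
#' @return Object of class `acc_curve`: list with `criterion`, `accuracy`
#'   and `n_trials`.
#' @export
acc_curve <- function(scores, truth, criteria = seq(0, 1, by = 0.01)) {
  if (length(scores) == 0L)
    palp_stop("at least one trial is required", "palp_parameter_error")
  if (length(scores) != length(truth))
    palp_stop("scores and truth must have the same length", "palp_shape_error")
  truth <- as.logical(truth)
  acc <- vapply(criteria, function(cj) mean(decide(scores, cj) == truth),
                numeric(1))
  structure(list(criterion = criteria, accuracy = acc,
                 n_trials = length(scores)),
            class = "acc_curve")
}

#' @export
print.acc_curve <- function(x, ...) {
  cat(sprintf("Accuracy-vs-criterion curve: %d grid points, %d trials, max accuracy %.3f at c = %.2f\n",
              length(x$criterion), x$n_trials, max(x$accuracy),
              x$criterion[which.max(x$accuracy)]))
  invisible(x)
}

#' @export
plot.acc_curve <- function(x, ...) {
  plot.default(x$criterion, x$accuracy, type = "l", ylim = c(0, 1),
               xlab = "detection criterion", ylab = "accuracy",
               main = "Accuracy vs detection criterion", ...)
  abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Threshold detection criterion from an accuracy curve
#'
#' The accuracy threshold is set a tenth of the way down from the maximum
#' toward chance, `ACC_th = max(ACC) - (max(ACC) - 0.5) / 10`. The lower
#' and upper criteria are the smallest and largest grid criteria whose
#' accuracy reaches `ACC_th` (the qualifying set is never empty because the
#' maximizer qualifies; non-contiguous super-threshold regions are handled
#' by taking the global extremes). The threshold criterion is their
#' midpoint. Applying it to the calibration data itself yields an accuracy
#' of at least `ACC_th`.
#'
#' @param curve An [acc_curve()].
#' @return Object of class `detection_criterion`: list with `c_th`, `c_l`,
#'   `c_u`, `acc_th` and `acc_max`. A curve whose maximum accuracy is below
#'   0.5 signals a degenerate model and triggers a warning (the criterion
#'   is still computed).
#' @export
threshold_criterion <- function(curve) {
  if (!inherits(curve, "acc_curve"))
    palp_stop("curve must be an acc_curve object", "palp_parameter_error")
  acc_max <- max(curve$accuracy)
  if (acc_max < 0.5)
    warning("maximum accuracy is below chance level (0.5); the model looks degenerate")
  acc_th <- acc_max - (acc_max - 0.5) / 10
  # for a below-chance curve acc_th exceeds the maximum; the maximizer must
  # still qualify or no criterion could be computed
  qual <- curve$accuracy >= min(acc_th, acc_max) - 1e-9
  c_l <- min(curve$criterion[qual])
  c_u <- max(curve$criterion[qual])
  structure(list(c_th = (c_l + c_u) / 2, c_l = c_l, c_u = c_u,
                 acc_th = acc_th, acc_max = acc_max),
            class = "detection_criterion")
}

#' @export
print.detection_criterion <- function(x, ...) {
  cat(sprintf("Detection criterion c_th = %.3f (c_l = %.2f, c_u = %.2f; ACC_th = %.3f of max %.3f)\n",
              x$c_th, x$c_l, x$c_u, x$acc_th, x$acc_max))
  invisible(x)
}
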