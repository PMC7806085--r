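#' Hit and false-alarm rates at one criterion
#'
#' Signal-detection rates under the strict-greater decision rule: the hit
#' rate is the fraction of tumor-present trials detected, the false-alarm
#' rate the fraction of tumor-absent trials detected.
#'
#' @param scores Representative scores, one per trial.
#' @param truth Logical tumor presence, same length; both classes must be
#'   represented (rates are undefined otherwise).
#' @param criterion Detection criterion in `[0, 1]`.
#' @return Named list with components `F` (false-alarm rate) and `H` (hit
#'   rate).
#' @export
sdt_rates <- function(scores, truth, criterion) {
  truth <- as.logical(truth)
  if (!any(truth) || !any(!truth))
    palp_stop("both tumor-present and tumor-absent trials are required; rates are undefined otherwise",
              "palp_parameter_error")
  det <- decide(scores, criterion)
  list(F = mean(det[!truth]), H = mean(det[truth]))
}

#' Empirical ROC curve over the criterion grid
#'
#' Sweeps the same 101-point criterion grid as [acc_curve()], collects the
#' `(F_j, H_j)` pairs, appends the anchor points (0,0) and (1,1) when they
#' are not already reached (the strict-greater rule cannot produce
#' `F = H = 1` when some scores are exactly 0), and sorts by `F` (ties by
#' `H`) for area computation.
#'
#' @inheritParams sdt_rates
#' @param criteria Criterion grid.
#' @return Object of class `roc_curve`: list with the grid rates `F`, `H`,
#'   the sorted `points` matrix (anchors included) and the trapezoidal area
#'   `auc`.
#' @export
roc_curve <- function(scores, truth, criteria = seq(0, 1, by = 0.01)) {
  truth <- as.logical(truth)
  if (!any(truth) || !any(!truth))
    palp_stop("both tumor-present and tumor-absent trials are required",
              "palp_parameter_error")
  H <- vapply(criteria, function(cj) mean(scores[truth] > cj), numeric(1))
  F <- vapply(criteria, function(cj) mean(scores[!truth] > cj), numeric(1))
  Fp <- F
  Hp <- H
  if (!any(F == 0 & H == 0)) { Fp <- c(Fp, 0); Hp <- c(Hp, 0) }
  if (!any(F == 1 & H == 1)) { Fp <- c(Fp, 1); Hp <- c(Hp, 1) }
  ord <- order(Fp, Hp)
  points <- cbind(F = Fp[ord], H = Hp[ord])
  structure(list(criterion = criteria, F = F, H = H, points = points,
                 auc = roc_area(points)),
            class = "roc_curve")
}

#' Area under an ROC curve
#'
#' The default is the trapezoid rule over consecutive sorted pairs,
#' `A_g = 1/2 * sum((F[j+1] - F[j]) * (H[j+1] + H[j]))`, which gives 1 for
#' the unit-square curve and 0.5 for the diagonal. Method
#' `"increment_product"` is the non-standard variant
#' `1/2 * sum(dF * dH)` (pairing the increments instead of averaging the
#' heights); it is not a proper area — it yields 0 on the unit square — and
#' is retained only for comparison experiments.
#'
#' @param x A [roc_curve()] or a two-column matrix of sorted `(F, H)` pairs
#'   including the anchors.
#' @param method `"trapezoid"` (default) or `"increment_product"`.
#' @return Scalar area.
#' @export
roc_area <- function(x, method = c("trapezoid", "increment_product")) {
  method <- match.arg(method)
  pts <- if (inherits(x, "roc_curve")) x$points else as.matrix(x)
  if (is.unsorted(pts[, 1L]))
    palp_stop("ROC pairs must be sorted by false-alarm rate", "palp_internal_error")
  dF <- diff(pts[, 1L])
  if (method == "trapezoid") {
    sum(dF * (pts[-1L, 2L] + pts[-nrow(pts), 2L])) / 2
  } else {
    sum(dF * diff(pts[, 2L])) / 2
  }
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d criterion grid points, A_g = %.4f\n",
              length(x$criterion), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot.default(x$points[, "F"], x$points[, "H"], type = "l",
               xlim = c(0, 1), ylim = c(0, 1),
               xlab = "false-alarm rate F", ylab = "hit rate H",
               main = sprintf("ROC (A_g = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}
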