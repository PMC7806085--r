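#' Fuse overlapping window outputs into a per-sample score series
#'
#' Each sample of the trial is covered by up to `T_w / (T_w - T_o)` windows
#' (ten with the defaults); its score is the arithmetic mean of the
#' corresponding components of all covering window outputs. Edge samples are
#' averaged over however many windows cover them, so the trial boundaries
#' are not discarded.
#'
#' @param prob Numeric `n_windows x width` matrix of window output
#'   probabilities, rows ordered as the window starts of
#'   [extract_windows()].
#' @param cfg The [extraction_config()] used for extraction.
#' @param L Trial length in samples.
#' @return Numeric vector of per-sample mean probabilities over the covered
#'   region (length `(n_windows - 1) * shift + width`).
#' @export
per_sample_scores <- function(prob, cfg, L) {
  prob <- as.matrix(prob)
  starts <- window_starts(L, cfg)
  if (nrow(prob) != length(starts))
    palp_stop(sprintf("%d window outputs supplied but a %d-sample trial yields %d windows",
                      nrow(prob), L, length(starts)), "palp_shape_error")
  if (ncol(prob) != cfg$width)
    palp_stop(sprintf("window outputs have %d samples but the configuration expects %d",
                      ncol(prob), cfg$width), "palp_shape_error")
  Lc <- starts[length(starts)] + cfg$width - 1L
  sums <- numeric(Lc)
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + cfg$width - 1L)
    sums[idx] <- sums[idx] + prob[i, ]
  }
  sums / coverage_counts(L, cfg)[seq_len(Lc)]
}

#' Maximum score within each scanning segment
#'
#' @param scores Per-sample score series from [per_sample_scores()].
#' @param segments Matrix with `start`/`end` columns (1-based inclusive),
#'   e.g. from [extract_scan_segments()] or a trial's `true_segments`.
#' @return Numeric vector with one maximum per segment, in segment order.
#'   Segments extending past the covered region are clipped; an empty (or
#'   fully clipped) segment list is an error of class `palp_no_scan_error`
#'   because the trial cannot be scored without a scan.
#' @export
scan_maxima <- function(scores, segments) {
  segments <- as.matrix(segments)
  if (nrow(segments) == 0L)
    palp_stop("no scanning segments: the trial cannot be scored",
              "palp_no_scan_error")
  L <- length(scores)
  keep <- segments[, 1L] <= L
  segments <- segments[keep, , drop = FALSE]
  if (nrow(segments) == 0L)
    palp_stop("all scanning segments lie beyond the scored region",
              "palp_no_scan_error")
  vapply(seq_len(nrow(segments)), function(i) {
    max(scores[segments[i, 1L]:min(segments[i, 2L], L)])
  }, numeric(1))
}

#' Representative estimation score of a trial
#'
#' The mean of the per-segment maximum scores: one scalar in `[0, 1]`
#' summarizing the whole trial, comparable to a participant's single
#' detection response.
#'
#' @param maxima Numeric vector of per-segment maxima from [scan_maxima()].
#' @return Scalar mean.
#' @export
representative_score <- function(maxima) {
  if (length(maxima) == 0L)
    palp_stop("no scan maxima: the trial cannot be scored", "palp_no_scan_error")
  mean(maxima)
}

#' Apply a detection criterion to a representative score
#'
#' A trial is declared tumor-positive when its representative score is
#' strictly larger than the criterion; equality counts as no detection (the
#' conservative reading of a larger/smaller rule).
#'
#' @param representative Representative score(s) in `[0, 1]`.
#' @param criterion Detection criterion in `[0, 1]`.
#' @return Logical detection decision(s).
#' @export
decide <- function(representative, criterion) {
  if (any(representative < 0 | representative > 1) ||
      any(criterion < 0 | criterion > 1))
    palp_stop("scores and criteria must lie in [0, 1]", "palp_parameter_error")
  representative > criterion
}

#' Score one trial with one or several fitted segmenters
#'
#' Runs the full per-trial pipeline: window extraction, network prediction,
#' overlap averaging into a score series, per-scanning-segment maxima and
#' the representative score. When several models are supplied their score
#' series are averaged (ensemble mean) before the maxima are taken.
#'
#' @param model A [dnn_segmenter()] or a list of them.
#' @param trial A `trial_record`.
#' @param cfg An [extraction_config()].
#' @param segments Optional precomputed segment matrix; overrides detection.
#' @param use_true_segments Use the simulator's ground-truth stroke segments
#'   instead of detecting scanning segments from the tangential force
#'   (isolates scoring from segmentation in tests).
#' @param windows Optional precomputed [extract_windows()] result for this
#'   trial (saves repeated extraction when scoring with many models).
#' @param ... Passed to [extract_scan_segments()].
#' @return List of class `trial_score`: `series`, `segments`, `maxima`,
#'   `representative`.
#' @export
score_trial <- function(model, trial, cfg, segments = NULL,
                        use_true_segments = FALSE, windows = NULL, ...) {
  if (inherits(model, "dnn_segmenter")) model <- list(model)
  if (is.null(windows)) windows <- extract_windows(trial, cfg)
  series <- 0
  for (m in model)
    series <- series + per_sample_scores(predict(m, windows$x), cfg, windows$L)
  series <- series / length(model)
  if (is.null(segments)) {
    segments <- if (use_true_segments) trial$true_segments
                else extract_scan_segments(trial, ...)
  }
  maxima <- scan_maxima(series, segments)
  structure(list(series = series, segments = segments, maxima = maxima,
                 representative = representative_score(maxima)),
            class = "trial_score")
}

#' @export
print.trial_score <- function(x, ...) {
  cat(sprintf("Trial score: representative %.3f over %d scanning segment(s) (maxima: %s)\n",
              x$representative, length(x$maxima),
              paste(sprintf("%.3f", x$maxima), collapse = ", ")))
  invisible(x)
}
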