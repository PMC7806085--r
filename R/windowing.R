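#' Sliding-window extraction settings
#'
#' The sensor trace is cut into fixed-width windows of `T_w` seconds that
#' overlap the previous window by `T_o` seconds, so consecutive windows are
#' shifted by `T_w - T_o` seconds. With the defaults (1.0 s window, 0.9 s
#' overlap) a new window is available every 0.1 s — a 10 Hz refresh rate —
#' and every steady-state sample is contained in ten windows.
#'
#' @param T_w Window width in seconds.
#' @param T_o Overlap in seconds; `0 <= T_o < T_w` and
#'   `(T_w - T_o) * sampling_rate` must be a positive integer.
#' @param sampling_rate Sampling frequency in Hz of the traces to be cut.
#' @return An object of class `extraction_config` with derived integer
#'   fields `width` (window length in samples) and `shift` (samples between
#'   consecutive window starts).
#' @export
extraction_config <- function(T_w = 1.0, T_o = 0.9, sampling_rate = 1000) {
  if (T_o < 0 || T_o >= T_w)
    palp_stop("need 0 <= T_o < T_w", "palp_parameter_error")
  width <- T_w * sampling_rate
  shift <- (T_w - T_o) * sampling_rate
  if (abs(width - round(width)) > 1e-8 || round(width) < 1)
    palp_stop("T_w * sampling_rate must be a positive integer (window width in samples)",
              "palp_parameter_error")
  if (abs(shift - round(shift)) > 1e-8 || round(shift) < 1)
    palp_stop("(T_w - T_o) * sampling_rate must be a positive integer (window shift in samples)",
              "palp_parameter_error")
  structure(list(T_w = T_w, T_o = T_o, sampling_rate = sampling_rate,
                 width = as.integer(round(width)),
                 shift = as.integer(round(shift))),
            class = "extraction_config")
}

window_starts <- function(L, cfg) {
  if (L < cfg$width) return(integer(0))
  n <- (L - cfg$width) %/% cfg$shift + 1L
  1L + cfg$shift * (seq_len(n) - 1L)
}

#' Extract overlapping sensor/label window pairs from a trial
#'
#' Cuts the sensor trace and the binary tumor-label trace of a trial into
#' aligned overlapping windows. Windows start at samples `1, 1+s, 1+2s, ...`
#' where `s` is the shift in samples; trailing samples that do not fill a
#' complete window are left to be covered by earlier windows only (the
#' network input dimension is fixed at the window width, so no partial
#' windows are created).
#'
#' @param trial A `trial_record` (or any list with numeric `sensor` and
#'   `tumor_label` components of equal length).
#' @param cfg An [extraction_config()].
#' @return An object of class `window_set`: list with `x` and `t` matrices
#'   (one window per row), integer `starts` (1-based first sample of each
#'   window), the `cfg`, and the trial length `L`.
#' @export
extract_windows <- function(trial, cfg) {
  x <- trial$sensor
  lab <- trial$tumor_label
  if (length(x) != length(lab))
    palp_stop("sensor and tumor_label traces differ in length", "palp_shape_error")
  L <- length(x)
  if (L < cfg$width)
    palp_stop(sprintf(
      "trial has %d samples but one window needs %d: nothing can be extracted",
      L, cfg$width), "palp_parameter_error")
  starts <- window_starts(L, cfg)
  idx <- outer(starts, 0:(cfg$width - 1L), `+`)
  structure(list(x = matrix(x[idx], nrow = length(starts)),
                 t = matrix(as.integer(lab[idx]), nrow = length(starts)),
                 starts = starts, cfg = cfg, L = L),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("%d window(s) of %d samples (shift %d) from a %d-sample trial\n",
              length(x$starts), x$cfg$width, x$cfg$shift, x$L))
  invisible(x)
}

#' Per-sample count of covering windows
#'
#' For a trial of `L` samples, returns how many extracted windows contain
#' each sample. Counts ramp up at the start of the trial, sit at
#' `T_w / (T_w - T_o)` (ten with the defaults) in steady state, and fall off
#' at the end; samples beyond the last complete window have count zero.
#'
#' @param L Trial length in samples.
#' @param cfg An [extraction_config()].
#' @return Integer vector of length `L`.
#' @export
coverage_counts <- function(L, cfg) {
  if (L < cfg$width)
    palp_stop(sprintf("trial has %d samples but one window needs %d", L, cfg$width),
              "palp_parameter_error")
  starts <- window_starts(L, cfg)
  d <- integer(L + 1L)
  for (s in starts) {
    d[s] <- d[s] + 1L
    d[s + cfg$width] <- d[s + cfg$width] - 1L
  }
  cumsum(d[seq_len(L)])
}

#' Extract scanning segments from the tangential contact force
#'
#' The time the probe spends scanning the phantom is recovered from the
#' tangential force: maximal runs of samples whose force exceeds
#' `threshold_fraction` of the trial's maximum force, merged across gaps
#' shorter than `merge_gap` seconds, and kept only if they last at least
#' `min_duration` seconds. An all-zero force trace yields no segments.
#'
#' @param x A `trial_record`, or a non-negative numeric force vector (then
#'   `sampling_rate` is required).
#' @param threshold_fraction Fraction of the maximum force used as the
#'   contact threshold.
#' @param min_duration Minimum segment duration in seconds.
#' @param merge_gap Sub-threshold gaps shorter than this (seconds) are
#'   bridged before the duration filter.
#' @param sampling_rate Sampling frequency in Hz (taken from the trial when
#'   `x` is a `trial_record`).
#' @return Integer matrix with columns `start`, `end` (1-based, inclusive),
#'   one row per scanning segment, sorted and disjoint.
#' @export
extract_scan_segments <- function(x, threshold_fraction = 0.1,
                                  min_duration = 0.3, merge_gap = 0.1,
                                  sampling_rate = NULL) {
  if (inherits(x, "trial_record") || (is.list(x) && !is.null(x$tangential_force))) {
    force <- x$tangential_force
    sampling_rate <- x$sampling_rate
  } else {
    force <- x
    if (is.null(sampling_rate))
      palp_stop("sampling_rate is required when passing a raw force vector",
                "palp_parameter_error")
  }
  if (any(force < 0))
    palp_stop("tangential force must be non-negative", "palp_parameter_error")
  empty <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  mx <- max(force)
  if (mx <= 0) return(empty)
  above <- force > threshold_fraction * mx
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(start = starts[r$values], end = ends[r$values])
  if (nrow(seg) == 0L) return(empty)
  # bridge short sub-threshold gaps, then drop short runs
  gap_max <- merge_gap * sampling_rate
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
    if (seg[i, "start"] - merged[nrow(merged), "end"] - 1L < gap_max) {
      merged[nrow(merged), "end"] <- seg[i, "end"]
    } else {
      merged <- rbind(merged, seg[i, , drop = FALSE])
    }
  }
  keep <- (merged[, "end"] - merged[, "start"] + 1L) >= min_duration * sampling_rate
  out <- merged[keep, , drop = FALSE]
  if (nrow(out) == 0L) empty else out
}
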