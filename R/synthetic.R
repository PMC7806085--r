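#' Scanning profile for the synthetic phantom generator
#'
#' Describes how one simulated participant scans the stomach-wall phantom with
#' the tactile sensor probe: how many scanning strokes a trial contains, how
#' long a stroke lasts, how strongly the probe presses, and what the tumor
#' signature looks like when the probe crosses it. A stroke contributes a
#' half-sine contact bump to the sensor trace and a raised tangential-force
#' interval; crossing the toroidal tumor adds two Gaussian-shaped peaks (its
#' two edges) separated by `tumor_peak_separation`. Sensor units are
#' arbitrary, with the contact baseline near 1.
#'
#' The defaults encode the recording conditions the generator emulates:
#' 1 kHz sampling, a 10 Hz low-pass filter, and visible inter-participant
#' variation in speed and applied force.
#'
#' @param n_strokes Number of scanning strokes per trial (>= 1).
#' @param stroke_duration Nominal stroke duration in seconds.
#' @param baseline_force Amplitude of the half-sine contact bump in the
#'   sensor trace (arbitrary sensor units).
#' @param tumor_peak_amplitude Amplitude of each tumor-edge peak (sensor
#'   units) added on top of the contact bump.
#' @param tumor_peak_separation Time in seconds between the two tumor-edge
#'   peaks at nominal stroke speed; must be smaller than `stroke_duration`.
#' @param noise_sd Standard deviation of additive sensor noise (before
#'   low-pass filtering), sensor units.
#' @param sampling_rate Sampling frequency in Hz; must exceed twice
#'   `lowpass_cutoff`.
#' @param lowpass_cutoff Cut-off frequency in Hz of the zero-phase
#'   second-order Butterworth filter applied to the sensor trace.
#' @param speed_jitter Relative standard deviation of stroke duration and
#'   inter-stroke gaps (inter-stroke / inter-trial variation).
#' @param force_jitter Relative standard deviation of per-stroke applied
#'   force.
#' @return An object of class `scan_profile`.
#' @seealso [generate_trial()], [generate_participant()], [generate_cohort()]
#' @export
scan_profile <- function(n_strokes = 3,
                         stroke_duration = 1,
                         baseline_force = 1,
                         tumor_peak_amplitude = 0.8,
                         tumor_peak_separation = 0.3,
                         noise_sd = 0.05,
                         sampling_rate = 1000,
                         lowpass_cutoff = 10,
                         speed_jitter = 0.1,
                         force_jitter = 0.1) {
  if (!is.numeric(n_strokes) || n_strokes < 1)
    palp_stop("n_strokes must be >= 1", "palp_parameter_error")
  if (any(c(baseline_force, tumor_peak_amplitude, tumor_peak_separation,
            noise_sd, speed_jitter, force_jitter) < 0))
    palp_stop("amplitudes, noise_sd and jitters must be non-negative",
              "palp_parameter_error")
  if (stroke_duration <= 0)
    palp_stop("stroke_duration must be positive", "palp_parameter_error")
  if (sampling_rate <= 2 * lowpass_cutoff)
    palp_stop("sampling_rate must exceed twice the low-pass cutoff (Nyquist)",
              "palp_parameter_error")
  if (tumor_peak_separation >= stroke_duration)
    palp_stop("tumor_peak_separation must be smaller than stroke_duration",
              "palp_parameter_error")
  structure(list(n_strokes = as.integer(n_strokes),
                 stroke_duration = stroke_duration,
                 baseline_force = baseline_force,
                 tumor_peak_amplitude = tumor_peak_amplitude,
                 tumor_peak_separation = tumor_peak_separation,
                 noise_sd = noise_sd,
                 sampling_rate = sampling_rate,
                 lowpass_cutoff = lowpass_cutoff,
                 speed_jitter = speed_jitter,
                 force_jitter = force_jitter),
            class = "scan_profile")
}

#' @export
print.scan_profile <- function(x, ...) {
  cat("Synthetic phantom-scan profile\n")
  cat(sprintf("  strokes/trial: %d x %.2f s, baseline %.2f, tumor peaks %.2f (sep %.2f s)\n",
              x$n_strokes, x$stroke_duration, x$baseline_force,
              x$tumor_peak_amplitude, x$tumor_peak_separation))
  cat(sprintf("  sampling %g Hz, low-pass %g Hz, noise sd %.3f, jitter speed %.2f / force %.2f\n",
              x$sampling_rate, x$lowpass_cutoff, x$noise_sd,
              x$speed_jitter, x$force_jitter))
  invisible(x)
}

# zero-phase 2nd-order Butterworth low-pass
lowpass <- function(x, cutoff, sampling_rate) {
  bf <- signal::butter(2, cutoff / (sampling_rate / 2), type = "low")
  signal::filtfilt(bf, x)
}

#' Generate one synthetic detection trial
#'
#' Simulates one phantom-scan trial: a series of scanning strokes, each
#' producing a half-sine contact bump in the sensor trace and a raised
#' tangential-force interval, separated by gaps of no contact. When
#' `tumor_present` is `TRUE` every stroke crosses the toroidal tumor, adding
#' two Gaussian-shaped peaks to the sensor trace and setting the binary tumor
#' label to 1 over the crossing interval. Gaussian noise is added to the
#' sensor trace, which is then low-pass filtered (zero-phase) at the
#' profile's cut-off frequency; the label trace is not filtered.
#'
#' @param profile A [scan_profile()].
#' @param tumor_present Logical ground truth for the trial.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so that callers such as [generate_participant()] stay
#'   reproducible from a single seed).
#' @param participant_id,trial_index Identifiers stored in the record.
#' @return An object of class `trial_record` with components `sensor`
#'   (filtered trace), `tumor_label` (0/1 integers, same length),
#'   `tangential_force` (non-negative, same length), `tumor_present`,
#'   `true_segments` (matrix of 1-based inclusive `[start, end]` sample
#'   indices of the strokes), `clean` (the noise-free filtered envelope,
#'   simulation ground truth), `sampling_rate`, `profile` and identifiers.
#' @export
generate_trial <- function(profile, tumor_present, seed = NULL,
                           participant_id = "P01", trial_index = 1L) {
  if (!inherits(profile, "scan_profile"))
    palp_stop("profile must be a scan_profile object", "palp_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  sr <- profile$sampling_rate
  ns <- profile$n_strokes

  # per-stroke kinematics: durations and applied force scale with the
  # profile jitters; gaps are 0.2-0.5 s of no contact, fixed at 0.35 s when
  # speed_jitter is zero so jitter-free trials share one envelope
  dur <- profile$stroke_duration *
    pmax(0.3, 1 + rnorm(ns) * profile$speed_jitter)
  amp <- pmax(0.1, 1 + rnorm(ns) * profile$force_jitter)
  gaps <- pmin(0.5, pmax(0.2, 0.35 * (1 + rnorm(ns + 1) * profile$speed_jitter)))

  gap_s <- pmax(1L, as.integer(round(gaps * sr)))
  dur_s <- pmax(4L, as.integer(round(dur * sr)))
  L <- sum(gap_s) + sum(dur_s)

  clean <- numeric(L)
  tang <- numeric(L)
  label <- integer(L)
  segs <- matrix(0L, nrow = ns, ncol = 2L,
                 dimnames = list(NULL, c("start", "end")))

  pos <- 0L
  for (i in seq_len(ns)) {
    pos <- pos + gap_s[i]
    m <- dur_s[i]
    idx <- (pos + 1L):(pos + m)
    u <- (seq_len(m) - 1) / (m - 1)
    half_sine <- sin(pi * u)
    tang[idx] <- tang[idx] + amp[i] * half_sine
    clean[idx] <- clean[idx] + profile$baseline_force * amp[i] * half_sine
    if (isTRUE(tumor_present)) {
      # two tumor-edge peaks around the stroke centre; separation and peak
      # width scale with the realised stroke duration (slower pass = wider
      # signature in time)
      scale <- dur_s[i] / (profile$stroke_duration * sr)
      sep_s <- profile$tumor_peak_separation * sr * scale
      sigma <- (profile$stroke_duration / 10) * sr * scale
      centre <- (m - 1) / 2
      c1 <- centre - sep_s / 2
      c2 <- centre + sep_s / 2
      j <- seq_len(m) - 1
      bump <- profile$tumor_peak_amplitude * amp[i] *
        (exp(-(j - c1)^2 / (2 * sigma^2)) + exp(-(j - c2)^2 / (2 * sigma^2)))
      clean[idx] <- clean[idx] + bump
      lab_lo <- max(1L, as.integer(ceiling(c1 - sigma)) + 1L)
      lab_hi <- min(m, as.integer(floor(c2 + sigma)) + 1L)
      label[idx[lab_lo:lab_hi]] <- 1L
    }
    segs[i, ] <- c(pos + 1L, pos + m)
    pos <- pos + m
  }

  noisy <- clean + rnorm(L, 0, profile$noise_sd)
  structure(list(participant_id = participant_id,
                 trial_index = as.integer(trial_index),
                 tumor_present = isTRUE(tumor_present),
                 sensor = lowpass(noisy, profile$lowpass_cutoff, sr),
                 tumor_label = label,
                 tangential_force = tang,
                 true_segments = segs,
                 clean = lowpass(clean, profile$lowpass_cutoff, sr),
                 sampling_rate = sr,
                 profile = profile),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Trial %s/%d: %s, %d samples at %g Hz, %d stroke(s), %d labelled sample(s)\n",
              x$participant_id, x$trial_index,
              if (x$tumor_present) "tumor present" else "tumor absent",
              length(x$sensor), x$sampling_rate, nrow(x$true_segments),
              sum(x$tumor_label)))
  invisible(x)
}

#' Generate a balanced block of detection trials for one participant
#'
#' Produces `n_trials` trials — half with the tumor present, half without —
#' in randomized order, emulating a detection session of repeated scans.
#'
#' @param profile A [scan_profile()] describing this participant.
#' @param seed Optional integer seed.
#' @param participant_id Identifier stamped on every trial.
#' @param n_trials Even number of trials (default 40, i.e. 20 per class).
#' @return A list of [generate_trial()] records, with the seed stored as an
#'   attribute.
#' @export
generate_participant <- function(profile, seed = NULL,
                                 participant_id = "P01", n_trials = 40L) {
  if (n_trials < 2 || n_trials %% 2 != 0)
    palp_stop("n_trials must be an even count >= 2", "palp_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  truth <- sample(rep(c(TRUE, FALSE), each = n_trials / 2))
  trials <- lapply(seq_len(n_trials), function(i) {
    generate_trial(profile, truth[i], seed = NULL,
                   participant_id = participant_id, trial_index = i)
  })
  attr(trials, "seed") <- seed
  attr(trials, "participant_id") <- participant_id
  trials
}

#' Generate a multi-participant synthetic cohort
#'
#' Each participant receives a profile perturbed from `base_profile`
#' (applied force, tumor-peak amplitude, stroke duration and stroke count),
#' emulating the observation that applied force and scanning speed vary
#' between participants, then contributes one balanced block of trials.
#'
#' @param n_participants Number of participants (>= 2).
#' @param base_profile The cohort-level [scan_profile()].
#' @param inter_participant_sd Relative log-normal SD of the per-participant
#'   perturbation of force/amplitude/duration; 0 gives identical profiles.
#' @param seed Optional integer seed.
#' @param n_trials Trials per participant (even; default 40).
#' @return An object of class `palp_cohort`: a list with one element per
#'   participant, each a list of `trial_record`s.
#' @export
generate_cohort <- function(n_participants, base_profile = scan_profile(),
                            inter_participant_sd = 0.15, seed = NULL,
                            n_trials = 40L) {
  if (n_participants < 2)
    palp_stop("n_participants must be >= 2", "palp_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  cohort <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    f <- exp(rnorm(3, 0, inter_participant_sd))
    strokes <- base_profile$n_strokes
    if (inter_participant_sd > 0)
      strokes <- max(1L, strokes + sample(c(-1L, 0L, 0L, 1L), 1))
    prof <- scan_profile(n_strokes = strokes,
                         stroke_duration = base_profile$stroke_duration * f[3],
                         baseline_force = base_profile$baseline_force * f[1],
                         tumor_peak_amplitude = base_profile$tumor_peak_amplitude * f[2],
                         tumor_peak_separation = base_profile$tumor_peak_separation,
                         noise_sd = base_profile$noise_sd,
                         sampling_rate = base_profile$sampling_rate,
                         lowpass_cutoff = base_profile$lowpass_cutoff,
                         speed_jitter = base_profile$speed_jitter,
                         force_jitter = base_profile$force_jitter)
    cohort[[p]] <- generate_participant(prof, seed = NULL,
                                        participant_id = sprintf("P%02d", p),
                                        n_trials = n_trials)
  }
  structure(cohort, class = "palp_cohort", seed = seed)
}

#' @export
print.palp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants x %d trials\n",
              length(x), length(x[[1]])))
  invisible(x)
}
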