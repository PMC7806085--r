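test_that("tumor-absent trials carry an all-zero label and valid structure", {
  tr <- generate_trial(scan_profile(), FALSE, seed = 7)
  expect_true(all(tr$tumor_label == 0L))
  expect_length(tr$tumor_label, length(tr$sensor))
  expect_length(tr$tangential_force, length(tr$sensor))
  expect_true(all(tr$tangential_force >= 0))
})

test_that("tumor crossings show exactly two peaks above baseline + 3 noise SD", {
  prof <- scan_profile()
  for (seed in 1:3) {
    tr <- generate_trial(prof, TRUE, seed = seed)
    r <- rle(tr$tumor_label == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    expect_equal(nrow(runs), prof$n_strokes)
    thr <- prof$baseline_force + 3 * prof$noise_sd
    for (k in seq_len(nrow(runs))) {
      idx <- runs[k, 1]:runs[k, 2]
      x <- tr$sensor[idx]
      is_max <- x[2:(length(x) - 1)] > x[1:(length(x) - 2)] &
                x[2:(length(x) - 1)] > x[3:length(x)]
      n_peaks <- sum(is_max & x[2:(length(x) - 1)] > thr)
      expect_equal(n_peaks, 2L)
    }
  }
})

test_that("identical profile and seed reproduce the trial exactly", {
  prof <- desk_profile()
  a <- generate_trial(prof, TRUE, seed = 99)
  b <- generate_trial(prof, TRUE, seed = 99)
  expect_identical(a, b)
  pa <- generate_participant(prof, seed = 4)
  pb <- generate_participant(prof, seed = 4)
  expect_identical(pa, pb)
})

test_that("every labelled sample lies inside a true stroke segment", {
  tr <- generate_trial(desk_profile(n_strokes = 3), TRUE, seed = 21)
  lab <- which(tr$tumor_label == 1L)
  inside <- rep(FALSE, length(lab))
  for (k in seq_len(nrow(tr$true_segments)))
    inside <- inside | (lab >= tr$true_segments[k, 1] &
                        lab <= tr$true_segments[k, 2])
  expect_true(all(inside))
})

test_that("filtered sensor trace keeps >= 99% of its power below twice the cutoff", {
  prof <- scan_profile()
  tr <- generate_trial(prof, TRUE, seed = 13)
  x <- tr$sensor - mean(tr$sensor)
  L <- length(x)
  P <- Mod(fft(x))^2
  freq <- (seq_len(L) - 1) * prof$sampling_rate / L
  half <- 2:floor(L / 2)
  below <- sum(P[half][freq[half] < 2 * prof$lowpass_cutoff])
  expect_gte(below / sum(P[half]), 0.99)
})

test_that("a participant block is a randomized exact 20/20 split", {
  p <- generate_participant(desk_profile(), seed = 3)
  truth <- vapply(p, `[[`, logical(1), "tumor_present")
  expect_length(p, 40L)
  expect_equal(sum(truth), 20L)
  idx <- vapply(p, `[[`, integer(1), "trial_index")
  expect_equal(idx, 1:40)
})

test_that("zero jitter yields one shared noise-free envelope per class", {
  p <- generate_participant(desk_profile(speed_jitter = 0, force_jitter = 0),
                            seed = 8, n_trials = 8)
  truth <- vapply(p, `[[`, logical(1), "tumor_present")
  pres <- p[truth]
  for (tr in pres[-1]) {
    expect_identical(tr$true_segments, pres[[1]]$true_segments)
    expect_equal(tr$clean, pres[[1]]$clean)
  }
})

test_that("cohorts have the requested size and vary between seeds", {
  cohort <- generate_cohort(3, desk_profile(), seed = 31)
  expect_s3_class(cohort, "palp_cohort")
  expect_length(cohort, 3L)
  expect_true(all(lengths(cohort) == 40L))
  other <- generate_cohort(3, desk_profile(), seed = 32)
  expect_false(identical(cohort[[1]][[1]]$true_segments,
                         other[[1]][[1]]$true_segments))
  same <- generate_cohort(3, desk_profile(), inter_participant_sd = 0, seed = 31)
  profs <- lapply(same, function(p) p[[1]]$profile)
  expect_identical(profs[[1]], profs[[2]])
  expect_identical(profs[[1]], profs[[3]])
})

test_that("invalid profiles are rejected", {
  expect_error(scan_profile(noise_sd = -1), class = "palp_parameter_error")
  expect_error(scan_profile(sampling_rate = 15, lowpass_cutoff = 10),
               class = "palp_parameter_error")
  expect_error(scan_profile(n_strokes = 0), class = "palp_parameter_error")
  expect_error(generate_cohort(1, desk_profile()),
               class = "palp_parameter_error")
})
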