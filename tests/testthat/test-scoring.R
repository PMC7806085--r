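# 10-sample windows shifted by 1 sample: steady-state coverage of 10 with
# tiny traces, convenient for hand-checkable fusion arithmetic.
tiny_cfg <- function() extraction_config(1, 0.9, 10)

test_that("constant window outputs fuse to a constant score series", {
  cfg <- tiny_cfg()
  L <- 19L
  prob <- matrix(0.7, nrow = 10, ncol = 10)
  s <- per_sample_scores(prob, cfg, L)
  expect_length(s, 19L)
  expect_true(all(abs(s - 0.7) < 1e-12))
})

test_that("an interior sample covered by ten windows averages their outputs", {
  cfg <- tiny_cfg()
  L <- 19L
  prob <- matrix(0, nrow = 10, ncol = 10)
  # window i covers sample 10 at column 11 - i; plant 0.0, 0.1, ..., 0.9
  for (i in 1:10) prob[i, 11L - i] <- (i - 1) / 10
  s <- per_sample_scores(prob, cfg, L)
  expect_equal(s[10], 0.45)
  # sample 1 is covered by the first window only
  prob2 <- matrix(runif(100), nrow = 10)
  s2 <- per_sample_scores(prob2, cfg, L)
  expect_equal(s2[1], prob2[1, 1])
})

test_that("fusion equals a brute-force membership recomputation", {
  cfg <- desk_cfg()
  set.seed(14)
  for (L in c(40L, 97L, 160L)) {
    n <- length(brute_starts(L, 40L, 4L))
    prob <- matrix(runif(n * 40), nrow = n)
    s <- per_sample_scores(prob, cfg, L)
    starts <- brute_starts(L, 40L, 4L)
    Lc <- max(starts) + 39L
    oracle <- vapply(seq_len(Lc), function(k) {
      vals <- c()
      for (i in seq_along(starts))
        if (k >= starts[i] && k <= starts[i] + 39L)
          vals <- c(vals, prob[i, k - starts[i] + 1L])
      mean(vals)
    }, numeric(1))
    expect_equal(s, oracle)
  }
  expect_error(per_sample_scores(matrix(0.5, 3, 40), cfg, 160),
               class = "palp_shape_error")
})

test_that("raising a window output never lowers downstream scores", {
  cfg <- desk_cfg()
  set.seed(15)
  n <- length(brute_starts(120L, 40L, 4L))
  prob <- matrix(runif(n * 40, 0, 0.8), nrow = n)
  seg <- cbind(start = c(10L, 60L), end = c(50L, 110L))
  base_s <- per_sample_scores(prob, cfg, 120L)
  base_m <- scan_maxima(base_s, seg)
  for (k in 1:10) {
    up <- prob
    up[sample(n, 1), sample(40, 1)] <- 0.95
    s <- per_sample_scores(up, cfg, 120L)
    expect_true(all(s >= base_s - 1e-12))
    m <- scan_maxima(s, seg)
    expect_true(all(m >= base_m - 1e-12))
    expect_gte(representative_score(m), representative_score(base_m) - 1e-12)
  }
})

test_that("scan maxima pick the per-segment peak in order", {
  scores <- rep(0.3, 100)
  seg <- cbind(start = c(1L, 41L, 81L), end = c(30L, 70L, 100L))
  expect_equal(scan_maxima(scores, seg), rep(0.3, 3))
  scores[55] <- 0.95
  expect_equal(scan_maxima(scores, seg), c(0.3, 0.95, 0.3))
  expect_equal(scan_maxima(scores, cbind(start = 55L, end = 55L)), 0.95)
  expect_error(scan_maxima(scores, seg[0, , drop = FALSE]),
               class = "palp_no_scan_error")
})

test_that("the representative score is the segment-order-invariant mean of maxima", {
  expect_equal(representative_score(c(0.2, 0.8)), 0.5)
  expect_equal(representative_score(0.7), 0.7)
  expect_equal(representative_score(rep(0.4, 5)), 0.4)
  set.seed(16)
  m <- runif(6)
  expect_equal(representative_score(m), representative_score(rev(m)))
  expect_error(representative_score(numeric(0)), class = "palp_no_scan_error")
})

test_that("the detection rule is strictly greater-than", {
  expect_true(decide(0.9, 0.38))
  expect_false(decide(0.38, 0.38))
  expect_false(decide(0, 0))
  expect_error(decide(1.2, 0.5), class = "palp_parameter_error")
})

test_that("score_trial with ensemble models averages the score series", {
  prof <- desk_profile()
  cfg <- desk_cfg()
  tr <- generate_trial(prof, TRUE, seed = 30)
  ws <- extract_windows(tr, cfg)
  set.seed(31)
  m1 <- dnn_segmenter(ws$x, ws$t, control = dnn_control(epochs = 2))
  m2 <- dnn_segmenter(ws$x, ws$t, control = dnn_control(epochs = 2))
  s1 <- score_trial(m1, tr, cfg, use_true_segments = TRUE)
  s2 <- score_trial(m2, tr, cfg, use_true_segments = TRUE)
  se <- score_trial(list(m1, m2), tr, cfg, use_true_segments = TRUE)
  expect_equal(se$series, (s1$series + s2$series) / 2)
  # a trial with no contact cannot be scored
  tr$tangential_force[] <- 0
  expect_error(score_trial(m1, tr, cfg), class = "palp_no_scan_error")
})
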