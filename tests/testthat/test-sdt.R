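test_that("hit and false-alarm rates match direct counting", {
  scores <- c(rep(0.9, 20), rep(0.1, 20))
  truth <- rep(c(TRUE, FALSE), each = 20)
  r <- sdt_rates(scores, truth, 0.5)
  expect_equal(r$F, 0)
  expect_equal(r$H, 1)
  r0 <- sdt_rates(scores, truth, 0)
  expect_equal(r0, list(F = 1, H = 1))
  r1 <- sdt_rates(scores, truth, 1)
  expect_equal(r1, list(F = 0, H = 0))
  set.seed(19)
  sc <- runif(30)
  tr <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
  tr[1:2] <- c(TRUE, FALSE)
  for (cj in c(0.2, 0.5, 0.77)) {
    r <- sdt_rates(sc, tr, cj)
    expect_equal(r$H, sum(sc > cj & tr) / sum(tr))
    expect_equal(r$F, sum(sc > cj & !tr) / sum(!tr))
  }
  expect_error(sdt_rates(rep(0.5, 3), rep(TRUE, 3), 0.5),
               class = "palp_parameter_error")
})

test_that("separable scores give the unit-square curve with area 1", {
  scores <- c(rep(0.9, 20), rep(0.1, 20))
  truth <- rep(c(TRUE, FALSE), each = 20)
  roc <- roc_curve(scores, truth)
  expect_true(any(roc$points[, "F"] == 0 & roc$points[, "H"] == 1))
  expect_equal(roc$auc, 1)
})

test_that("identical scores collapse the curve to the diagonal anchors", {
  roc <- roc_curve(rep(0.6, 40), rep(c(TRUE, FALSE), each = 20))
  expect_equal(unique(roc$points), cbind(F = c(0, 1), H = c(0, 1)))
  expect_equal(roc$auc, 0.5)
})

test_that("hand-built curves integrate exactly", {
  square <- cbind(F = c(0, 0, 1), H = c(0, 1, 1))
  expect_equal(roc_area(square), 1)
  expect_equal(roc_area(square, method = "increment_product"), 0)
  diag_pts <- cbind(F = seq(0, 1, 0.25), H = seq(0, 1, 0.25))
  expect_equal(roc_area(diag_pts), 0.5)
})

test_that("grid ROC pairs match a brute-force grid evaluation", {
  set.seed(20)
  scores <- runif(24)
  truth <- sample(rep(c(TRUE, FALSE), 12))
  roc <- roc_curve(scores, truth)
  grid <- seq(0, 1, by = 0.01)
  expect_equal(roc$H, vapply(grid, function(c) mean(scores[truth] > c), 0))
  expect_equal(roc$F, vapply(grid, function(c) mean(scores[!truth] > c), 0))
})

test_that("rates are non-increasing in the criterion", {
  set.seed(21)
  for (k in 1:10) {
    scores <- runif(40)
    truth <- sample(rep(c(TRUE, FALSE), 20))
    roc <- roc_curve(scores, truth)
    expect_true(all(diff(roc$H) <= 0))
    expect_true(all(diff(roc$F) <= 0))
  }
})

test_that("the trapezoidal area is invariant under monotone transforms and class swap", {
  set.seed(22)
  truth <- sample(rep(c(TRUE, FALSE), 20))
  grid <- seq(0, 1, by = 0.01)
  k <- sample(1:50, 40, replace = TRUE)
  scores <- grid[k + 1]               # grid values 0.01 .. 0.50
  a <- roc_curve(scores, truth)$auc
  # a strictly increasing relabelling of the score values onto other grid
  # values (0.01k -> 0.02k) leaves the step curve, hence the area, unchanged
  expect_equal(roc_curve(grid[2 * k + 1], truth)$auc, a)
  # smooth monotone transforms move scores across grid bins, so invariance
  # holds to the grid resolution
  expect_lt(abs(roc_curve(scores^3, truth)$auc - a), 0.02)
  expect_lt(abs(roc_curve(plogis(scores * 4 - 2), truth)$auc - a), 0.02)
  expect_equal(roc_curve(scores, !truth)$auc, 1 - a, tolerance = 1e-10)
  expect_gte(a, 0)
  expect_lte(a, 1)
})

test_that("grid area agrees with the rank-based pairwise AUC oracle", {
  # scores are drawn at the criterion grid's own 0.01 resolution: the curve
  # then captures every distinct threshold and the trapezoid area must match
  # the pairwise-comparison AUC (ties counted 1/2)
  set.seed(23)
  for (k in 1:200) {
    n <- 2 * sample(5:25, 1)
    truth <- sample(rep(c(TRUE, FALSE), n / 2))
    scores <- sample(seq(0, 1, by = 0.01), n, replace = TRUE)
    a <- roc_curve(scores, truth)$auc
    expect_lt(abs(a - rank_auc(scores, truth)), 0.01)
  }
})

test_that("the grid area matches an established AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(24)
  scores <- runif(60)
  truth <- sample(rep(c(TRUE, FALSE), 30))
  a_ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
  expect_equal(roc_curve(scores, truth)$auc, a_ref, tolerance = 0.01)
})
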