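test_that("He initialization has the right scale and zero biases", {
  arch <- dnn_architecture(1000, c(2000, 8, 8))
  p <- init_dnn_params(arch, seed = 1)
  expect_equal(sd(p$W[[1]]), sqrt(2 / 1000), tolerance = 0.02)
  expect_equal(mean(p$W[[1]]), 0, tolerance = 2e-4)
  for (i in 1:4) expect_true(all(p$b[[i]] == 0))
  expect_identical(p, init_dnn_params(arch, seed = 1))
  expect_equal(dim(p$W[[1]]), c(2000L, 1000L))
  expect_equal(dim(p$W[[4]]), c(1000L, 8L))
})

test_that("forward pass matches an independent affine/ReLU/logistic oracle", {
  set.seed(2)
  arch <- dnn_architecture(4, c(8, 8, 8))
  p <- init_dnn_params(arch)
  x <- matrix(rnorm(12), nrow = 3)
  y <- dnn_forward(p, x)
  for (r in 1:3) {
    h <- x[r, ]
    for (i in 1:3) h <- pmax(as.vector(p$W[[i]] %*% h + p$b[[i]]), 0)
    z <- as.vector(p$W[[4]] %*% h + p$b[[4]])
    expect_equal(y[r, ], 1 / (1 + exp(-z)), tolerance = 1e-12)
  }
  expect_error(dnn_forward(p, rnorm(5)), class = "palp_shape_error")
})

test_that("all-zero parameters output 0.5 and outputs stay inside (0, 1)", {
  arch <- dnn_architecture(6, c(4, 4, 4))
  p <- init_dnn_params(arch, seed = 3)
  p0 <- p
  for (i in 1:4) p0$W[[i]][] <- 0
  expect_true(all(dnn_forward(p0, rnorm(6)) == 0.5))
  set.seed(4)
  for (k in 1:20) {
    q <- init_dnn_params(arch)
    y <- dnn_forward(q, matrix(rnorm(60) * 10^sample(-2:0, 1), ncol = 6))
    expect_true(all(y > 0 & y < 1))
  }
  # extreme input magnitudes saturate the logistic in floating point but
  # never leave [0, 1]
  yx <- dnn_forward(init_dnn_params(arch), matrix(rnorm(60) * 1e4, ncol = 6))
  expect_true(all(yx >= 0 & yx <= 1))
  # flipped output sign mirrors the standard logistic
  y1 <- dnn_forward(p, 1:6)
  y2 <- dnn_forward(p, 1:6, flip_output_sign = TRUE)
  expect_equal(y2, 1 - y1, tolerance = 1e-12)
})

test_that("cross-entropy reproduces hand-computed values in both modes", {
  expect_equal(cross_entropy(0.5, 1), log(2))
  expect_equal(cross_entropy(0.5, 1, "positive_only"), log(2))
  expect_equal(cross_entropy(c(0.5, 0.9), c(1, 0), "positive_only"), log(2))
  expect_equal(cross_entropy(c(0.5, 0.9), c(1, 0)), log(2) + log(10))
  eps <- 1e-12
  expect_equal(cross_entropy(c(eps, 1 - eps), c(0, 1)), 0, tolerance = 1e-10)
  expect_error(cross_entropy(c(0.1, 0.2), 1), class = "palp_shape_error")
})

test_that("analytic gradients match central finite differences", {
  set.seed(5)
  arch <- dnn_architecture(4, c(5, 5, 5))
  p <- init_dnn_params(arch)
  X <- matrix(rnorm(12), nrow = 4)   # 3 windows, column-major
  Tm <- matrix(rbinom(12, 1, 0.5), nrow = 4)
  for (mode in c("binary_cross_entropy", "positive_only")) {
    g <- palpassist:::.mlp_gradients(p, X, Tm, loss = mode)
    f <- function(q) cross_entropy(dnn_forward(q, t(X)), t(Tm), mode = mode)
    num <- numeric_gradients(p, f)
    for (i in 1:4) {
      expect_equal(g$dW[[i]], num$dW[[i]], tolerance = 1e-5)
      expect_equal(g$db[[i]], num$db[[i]], tolerance = 1e-5)
    }
  }
})

test_that("training reduces the loss and separates in- from out-of-tumor scores", {
  prof <- desk_profile()
  cfg <- desk_cfg()
  trials <- generate_participant(prof, seed = 6, n_trials = 12)
  ws <- lapply(trials, extract_windows, cfg = cfg)
  x <- do.call(rbind, lapply(ws, `[[`, "x"))
  tm <- do.call(rbind, lapply(ws, `[[`, "t"))
  fit <- dnn_segmenter(x, tm, control = dnn_control(epochs = 15, seed = 7))
  h <- fit$loss_history
  expect_length(h, 15L)
  expect_lt(h[15], h[1])
  y <- predict(fit, x)
  expect_gt(mean(y[tm == 1]), mean(y[tm == 0]))
})

test_that("zero epochs leave the initialized parameters untouched", {
  set.seed(8)
  x <- matrix(rnorm(80), nrow = 8)
  tm <- matrix(rbinom(80, 1, 0.3), nrow = 8)
  fit <- dnn_segmenter(x, tm, control = dnn_control(epochs = 0, seed = 11,
                                                    normalize = FALSE))
  expect_identical(fit$params,
                   init_dnn_params(dnn_architecture(10, c(20, 20, 20)), seed = 11))
  expect_length(fit$loss_history, 0L)
})

test_that("training is reproducible from the control seed", {
  set.seed(9)
  x <- matrix(rnorm(200), nrow = 20)
  tm <- matrix(rbinom(200, 1, 0.4), nrow = 20)
  ctl <- dnn_control(epochs = 3, batch_size = 7, seed = 12)
  a <- dnn_segmenter(x, tm, control = ctl)
  b <- dnn_segmenter(x, tm, control = ctl)
  expect_identical(a$params, b$params)
  expect_identical(a$loss_history, b$loss_history)
})

test_that("shape and label errors are classed", {
  x <- matrix(rnorm(40), nrow = 4)
  expect_error(dnn_segmenter(x, x[, -1]), class = "palp_shape_error")
  expect_error(dnn_segmenter(x, x), class = "palp_parameter_error")
  tm <- matrix(rbinom(40, 1, 0.5), nrow = 4)
  expect_error(dnn_segmenter(x, tm, arch = dnn_architecture(9, c(2, 2, 2))),
               class = "palp_shape_error")
  expect_error(dnn_architecture(4, c(2, 2)), class = "palp_parameter_error")
})
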