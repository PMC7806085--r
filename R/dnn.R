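#' Network architecture
#'
#' The segmenter is a fully connected feed-forward network with three hidden
#' ReLU layers mapping one sensor window to a same-length vector of
#' per-sample tumor probabilities. The reference geometry is a 1000-sample
#' input (one 1.0 s window at 1 kHz) with hidden layers of width 2000, i.e.
#' twice the input dimension; reduced desk-scale geometries should keep the
#' same 1:2 ratio.
#'
#' @param input_dim Window width in samples (also the output dimension).
#' @param hidden_dims Integer vector of exactly three hidden-layer widths.
#' @return An object of class `dnn_architecture`.
#' @export
dnn_architecture <- function(input_dim = 1000, hidden_dims = c(2000, 2000, 2000)) {
  input_dim <- as.integer(input_dim)
  hidden_dims <- as.integer(hidden_dims)
  if (length(hidden_dims) != 3L)
    palp_stop("hidden_dims must have length 3 (three hidden layers)",
              "palp_parameter_error")
  if (input_dim < 1L || any(hidden_dims < 1L))
    palp_stop("all layer dimensions must be >= 1", "palp_parameter_error")
  structure(list(input_dim = input_dim, hidden_dims = hidden_dims),
            class = "dnn_architecture")
}

#' Initialize network parameters
#'
#' He initialization for ReLU networks: each weight is drawn from a
#' zero-mean normal with standard deviation `sqrt(2 / fan_in)`; all biases
#' start at zero.
#'
#' @param arch A [dnn_architecture()].
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @return An object of class `dnn_params`: lists `W` and `b` of four weight
#'   matrices (output rows x input columns) and bias vectors, plus the layer
#'   dimension vector `dims`.
#' @export
init_dnn_params <- function(arch, seed = NULL) {
  if (!inherits(arch, "dnn_architecture"))
    palp_stop("arch must be a dnn_architecture object", "palp_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  dims <- c(arch$input_dim, arch$hidden_dims, arch$input_dim)
  W <- vector("list", 4L)
  b <- vector("list", 4L)
  for (i in 1:4) {
    fan_in <- dims[i]
    fan_out <- dims[i + 1L]
    W[[i]] <- matrix(rnorm(fan_out * fan_in, 0, sqrt(2 / fan_in)), fan_out, fan_in)
    b[[i]] <- numeric(fan_out)
  }
  structure(list(W = W, b = b, dims = dims), class = "dnn_params")
}

# forward pass on column-major batches (input_dim x batch); returns the
# output probabilities plus the pre-activations/activations needed by
# backpropagation
.mlp_forward <- function(params, X, flip = FALSE) {
  Zs <- vector("list", 3L)
  As <- vector("list", 3L)
  A <- X
  for (i in 1:3) {
    Z <- params$W[[i]] %*% A + params$b[[i]]
    A <- Z
    A[A < 0] <- 0
    Zs[[i]] <- Z
    As[[i]] <- A
  }
  Z4 <- params$W[[4]] %*% A + params$b[[4]]
  Y <- if (flip) plogis(-Z4) else plogis(Z4)
  list(Y = Y, Zs = Zs, As = As)
}

#' Raw forward pass of the segmenter network
#'
#' Applies the network to one window (vector) or a matrix of windows (one
#' per row): three affine + ReLU hidden layers followed by an element-wise
#' logistic, so every output component lies strictly in (0, 1) and can be
#' read as the probability that the corresponding sample carries tumor
#' information. `flip_output_sign = TRUE` selects the variant
#' `1 / (1 + exp(+z))` retained for fidelity experiments; the default is the
#' standard logistic `1 / (1 + exp(-z))`.
#'
#' No input normalization is applied here; use [predict.dnn_segmenter()] for
#' a fitted model, which replays its training normalization.
#'
#' @param params A [init_dnn_params()] object.
#' @param x Numeric vector of length `input_dim`, or an `n x input_dim`
#'   matrix.
#' @param flip_output_sign Use the sign-flipped logistic output.
#' @return Probability matrix of the same orientation as `x` (a vector in,
#'   a 1-row matrix out).
#' @export
dnn_forward <- function(params, x, flip_output_sign = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != params$dims[1L])
    palp_stop(sprintf("input has %d columns but the network expects %d",
                      ncol(x), params$dims[1L]), "palp_shape_error")
  t(.mlp_forward(params, t(x), flip_output_sign)$Y)
}

#' Cross-entropy between estimated and correct labels
#'
#' The default mode is the full binary cross-entropy
#' `E = -sum(t*log(y) + (1-t)*log(1-y))`; mode `"positive_only"` keeps only
#' the positive-class term `E = -sum(t*log(y))`, a degenerate variant whose
#' optimum is `y == 1` everywhere, retained for comparison experiments.
#' Probabilities are clipped to `[eps, 1-eps]` before taking logs. For
#' matrices (windows in rows) the summed loss is averaged over windows.
#'
#' @param y Estimated probabilities in (0, 1); vector or matrix.
#' @param t Binary correct labels, same shape.
#' @param mode `"binary_cross_entropy"` (default) or `"positive_only"`.
#' @param eps Clipping constant.
#' @return Scalar loss.
#' @export
cross_entropy <- function(y, t, mode = c("binary_cross_entropy", "positive_only"),
                          eps = 1e-12) {
  mode <- match.arg(mode)
  if (length(y) != length(t))
    palp_stop("y and t must have the same length", "palp_shape_error")
  n_obs <- if (is.matrix(y)) nrow(y) else 1L
  y <- pmin(pmax(y, eps), 1 - eps)
  E <- if (mode == "positive_only") {
    -sum(t * log(y))
  } else {
    -sum(t * log(y) + (1 - t) * log(1 - y))
  }
  E / n_obs
}

# analytic gradients by backpropagation through .mlp_forward; loss is the
# per-window mean so gradients are comparable across batch sizes
.mlp_gradients <- function(params, X, Tm, loss = "binary_cross_entropy",
                           flip = FALSE, eps = 1e-12) {
  B <- ncol(X)
  fw <- .mlp_forward(params, X, flip)
  Y <- fw$Y
  Yc <- pmin(pmax(Y, eps), 1 - eps)
  loss_val <- if (loss == "positive_only") {
    -sum(Tm * log(Yc)) / B
  } else {
    -(sum(Tm * log(Yc)) + sum((1 - Tm) * log(1 - Yc))) / B
  }
  # d loss / d z4: logistic + cross-entropy collapse to (y - t) for the
  # default pairing; positive-only keeps t*(y - 1); the flipped output
  # negates dy/dz
  G <- if (loss == "positive_only") Tm * (Y - 1) / B else (Y - Tm) / B
  if (flip) G <- -G
  dW <- vector("list", 4L)
  db <- vector("list", 4L)
  dW[[4]] <- G %*% t(fw$As[[3]])
  db[[4]] <- rowSums(G)
  D <- crossprod(params$W[[4]], G)
  for (i in 3:1) {
    D <- D * (fw$Zs[[i]] > 0)
    A_in <- if (i == 1L) X else fw$As[[i - 1L]]
    dW[[i]] <- D %*% t(A_in)
    db[[i]] <- rowSums(D)
    if (i > 1L) D <- crossprod(params$W[[i]], D)
  }
  list(dW = dW, db = db, loss = loss_val)
}

#' Training settings for the segmenter network
#'
#' Mini-batch Adam on shuffled windows. The reference schedule is 200 epochs
#' with mini-batches of 100 windows; Adam hyperparameters default to the
#' method's canonical values. The last, possibly short, batch of each epoch
#' is kept. Input normalization (a single z-score using the training set's
#' pooled mean and SD) is on by default because the sensor units are
#' arbitrary.
#'
#' @param epochs Passes over the training windows (>= 0; 0 leaves the
#'   freshly initialized parameters untouched).
#' @param batch_size Windows per mini-batch.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param loss See [cross_entropy()].
#' @param flip_output_sign See [dnn_forward()].
#' @param normalize Z-score the input windows with training-set statistics.
#' @param shuffle Reshuffle the windows every epoch.
#' @param seed Optional seed covering initialization and shuffling.
#' @return An object of class `dnn_control`.
#' @export
dnn_control <- function(epochs = 200, batch_size = 100, learning_rate = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                        loss = c("binary_cross_entropy", "positive_only"),
                        flip_output_sign = FALSE, normalize = TRUE,
                        shuffle = TRUE, seed = NULL) {
  loss <- match.arg(loss)
  if (epochs < 0) palp_stop("epochs must be >= 0", "palp_parameter_error")
  if (batch_size < 1) palp_stop("batch_size must be >= 1", "palp_parameter_error")
  if (learning_rate <= 0) palp_stop("learning_rate must be positive", "palp_parameter_error")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, loss = loss,
                 flip_output_sign = isTRUE(flip_output_sign),
                 normalize = isTRUE(normalize), shuffle = isTRUE(shuffle),
                 seed = seed),
            class = "dnn_control")
}

#' Fit the tumor-segmentation network
#'
#' Trains the three-hidden-layer feed-forward network that maps a sensor
#' window to per-sample tumor probabilities: He initialization, mini-batch
#' Adam on the (binary) cross-entropy, backpropagation through the exact
#' forward pass of [dnn_forward()]. This is the central fitting function of
#' the package; the returned object carries everything needed to score new
#' windows, including the training-set normalization statistics.
#'
#' @param x Numeric `n x W` matrix of sensor windows (one per row), e.g.
#'   `extract_windows(trial, cfg)$x`, possibly row-bound over trials.
#' @param labels Binary `n x W` matrix of aligned tumor labels.
#' @param arch A [dnn_architecture()]; when `NULL` a geometry with hidden
#'   layers twice the window width is derived from `ncol(x)`.
#' @param control A [dnn_control()].
#' @return An object of class `dnn_segmenter` with components `params`,
#'   `arch`, `control`, `normalization` (`mean`, `sd`), `loss_history`
#'   (per-epoch mean per-window loss) and `n_windows`.
#' @examples
#' prof <- scan_profile(sampling_rate = 40, noise_sd = 0.02, n_strokes = 2)
#' cfg <- extraction_config(1, 0.9, 40)
#' trials <- generate_participant(prof, seed = 1, n_trials = 6)
#' ws <- lapply(trials, extract_windows, cfg = cfg)
#' fit <- dnn_segmenter(do.call(rbind, lapply(ws, `[[`, "x")),
#'                      do.call(rbind, lapply(ws, `[[`, "t")),
#'                      control = dnn_control(epochs = 5, seed = 1))
#' fit
#' @export
dnn_segmenter <- function(x, labels, arch = NULL, control = dnn_control()) {
  x <- as.matrix(x)
  labels <- as.matrix(labels)
  if (!all(dim(x) == dim(labels)))
    palp_stop("x and labels must have identical dimensions", "palp_shape_error")
  if (nrow(x) < 1L)
    palp_stop("at least one window pair is required", "palp_parameter_error")
  if (!all(labels %in% c(0, 1)))
    palp_stop("labels must be binary (0/1)", "palp_parameter_error")
  W <- ncol(x)
  if (is.null(arch)) arch <- dnn_architecture(W, rep(2L * W, 3L))
  if (arch$input_dim != W)
    palp_stop(sprintf("windows have %d samples but the architecture expects %d",
                      W, arch$input_dim), "palp_shape_error")

  if (!is.null(control$seed)) set.seed(control$seed)
  norm <- list(mean = 0, sd = 1)
  if (control$normalize) {
    s <- sd(x)
    norm <- list(mean = mean(x), sd = if (is.finite(s) && s > 0) s else 1)
  }
  X <- t((x - norm$mean) / norm$sd)        # input_dim x n
  Tm <- t(labels)
  params <- init_dnn_params(arch)
  n <- ncol(X)

  mW <- lapply(params$W, function(w) array(0, dim(w)))
  vW <- lapply(params$W, function(w) array(0, dim(w)))
  mb <- lapply(params$b, function(b) numeric(length(b)))
  vb <- lapply(params$b, function(b) numeric(length(b)))
  step <- 0L
  lr <- control$learning_rate
  b1 <- control$beta1
  b2 <- control$beta2
  history <- numeric(control$epochs)

  for (ep in seq_len(control$epochs)) {
    ord <- if (control$shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0
    for (s0 in seq(1L, n, by = control$batch_size)) {
      idx <- ord[s0:min(s0 + control$batch_size - 1L, n)]
      g <- .mlp_gradients(params, X[, idx, drop = FALSE],
                          Tm[, idx, drop = FALSE],
                          control$loss, control$flip_output_sign)
      if (!is.finite(g$loss))
        palp_stop(paste("training diverged (non-finite loss); consider the",
                        "default binary_cross_entropy loss or a lower learning rate"),
                  "palp_training_error")
      ep_loss <- ep_loss + g$loss * length(idx)
      step <- step + 1L
      c1 <- 1 - b1^step
      c2 <- 1 - b2^step
      for (i in 1:4) {
        mW[[i]] <- b1 * mW[[i]] + (1 - b1) * g$dW[[i]]
        vW[[i]] <- b2 * vW[[i]] + (1 - b2) * g$dW[[i]]^2
        params$W[[i]] <- params$W[[i]] - lr * (mW[[i]] / c1) / (sqrt(vW[[i]] / c2) + control$epsilon)
        mb[[i]] <- b1 * mb[[i]] + (1 - b1) * g$db[[i]]
        vb[[i]] <- b2 * vb[[i]] + (1 - b2) * g$db[[i]]^2
        params$b[[i]] <- params$b[[i]] - lr * (mb[[i]] / c1) / (sqrt(vb[[i]] / c2) + control$epsilon)
      }
    }
    history[ep] <- ep_loss / n
  }

  structure(list(params = params, arch = arch, control = control,
                 normalization = norm, loss_history = history, n_windows = n),
            class = "dnn_segmenter")
}

#' Predict per-sample tumor probabilities for sensor windows
#'
#' @param object A fitted [dnn_segmenter()].
#' @param newdata Numeric vector of length `input_dim` or an
#'   `n x input_dim` matrix of windows.
#' @param ... Unused.
#' @return `n x input_dim` matrix of probabilities in (0, 1).
#' @export
predict.dnn_segmenter <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  z <- (newdata - object$normalization$mean) / object$normalization$sd
  dnn_forward(object$params, z, object$control$flip_output_sign)
}

#' @export
coef.dnn_segmenter <- function(object, ...) object$params

#' @export
print.dnn_segmenter <- function(x, ...) {
  dims <- x$params$dims
  cat(sprintf("Tumor-segmentation network: %s\n",
              paste(dims, collapse = " - ")))
  cat(sprintf("  trained on %d windows for %d epoch(s) (%s loss)\n",
              x$n_windows, length(x$loss_history), x$control$loss))
  if (length(x$loss_history))
    cat(sprintf("  mean per-window loss: first %.4f, final %.4f\n",
                x$loss_history[1], x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' @export
summary.dnn_segmenter <- function(object, ...) {
  n_par <- sum(vapply(object$params$W, length, 0)) +
    sum(vapply(object$params$b, length, 0))
  out <- list(dims = object$params$dims, n_parameters = n_par,
              epochs = length(object$loss_history),
              n_windows = object$n_windows,
              final_loss = if (length(object$loss_history))
                object$loss_history[length(object$loss_history)] else NA_real_,
              normalization = object$normalization,
              loss_mode = object$control$loss)
  class(out) <- "summary.dnn_segmenter"
  out
}

#' @export
print.summary.dnn_segmenter <- function(x, ...) {
  cat(sprintf("Layers: %s (%d parameters)\n", paste(x$dims, collapse = " - "),
              x$n_parameters))
  cat(sprintf("Trained %d epoch(s) on %d windows, %s loss, final loss %.4f\n",
              x$epochs, x$n_windows, x$loss_mode, x$final_loss))
  cat(sprintf("Input normalization: mean %.4f, sd %.4f\n",
              x$normalization$mean, x$normalization$sd))
  invisible(x)
}

#' @export
plot.dnn_segmenter <- function(x, ...) {
  if (!length(x$loss_history)) {
    warning("no training epochs recorded; nothing to plot")
    return(invisible(x))
  }
  plot.default(seq_along(x$loss_history), x$loss_history, type = "l",
               xlab = "epoch", ylab = "mean per-window loss",
               main = "Training loss", ...)
  invisible(x)
}
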