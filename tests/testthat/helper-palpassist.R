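# Shared fixtures, all generated in code.

# Desk-scale scanning profile: 40 Hz sampling keeps the 1.0 s / 0.9 s
# window geometry (width 40, shift 4, steady-state coverage 10) while
# trials stay small enough to train in seconds.
desk_profile <- function(...) {
  args <- list(...)
  defaults <- list(sampling_rate = 40, n_strokes = 2, noise_sd = 0.02,
                   tumor_peak_amplitude = 1)
  do.call(scan_profile, utils::modifyList(defaults, args))
}

desk_cfg <- function() extraction_config(1, 0.9, 40)

# Rank-based pairwise-comparison AUC (Mann-Whitney; ties count 1/2) —
# the independent oracle for the trapezoidal ROC area.
rank_auc <- function(scores, truth) {
  p <- scores[truth]
  a <- scores[!truth]
  mean(outer(p, a, `>`) + 0.5 * outer(p, a, `==`))
}

# Brute-force sliding-window enumeration: every valid start offset.
brute_starts <- function(L, W, s) {
  st <- integer(0)
  k <- 1L
  while (k + W - 1L <= L) {
    st <- c(st, k)
    k <- k + s
  }
  st
}

brute_coverage <- function(L, W, s) {
  cov <- integer(L)
  for (k in brute_starts(L, W, s)) {
    idx <- k:(k + W - 1L)
    cov[idx] <- cov[idx] + 1L
  }
  cov
}

# A minimal trial-like stub (enough for plan construction).
stub_trials <- function(n = 40) {
  truth <- rep(c(TRUE, FALSE), each = n / 2)
  lapply(seq_len(n), function(i) list(tumor_present = truth[i]))
}

# Central finite-difference gradient of f at params, all parameters.
numeric_gradients <- function(params, f, h = 1e-6) {
  g <- list(dW = vector("list", 4), db = vector("list", 4))
  for (i in 1:4) {
    gW <- array(0, dim(params$W[[i]]))
    for (j in seq_along(gW)) {
      up <- params; up$W[[i]][j] <- up$W[[i]][j] + h
      dn <- params; dn$W[[i]][j] <- dn$W[[i]][j] - h
      gW[j] <- (f(up) - f(dn)) / (2 * h)
    }
    g$dW[[i]] <- gW
    gb <- numeric(length(params$b[[i]]))
    for (j in seq_along(gb)) {
      up <- params; up$b[[i]][j] <- up$b[[i]][j] + h
      dn <- params; dn$b[[i]][j] <- dn$b[[i]][j] - h
      gb[j] <- (f(up) - f(dn)) / (2 * h)
    }
    g$db[[i]] <- gb
  }
  g
}
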