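.trial_truth <- function(trials)
  vapply(trials, function(tr) isTRUE(tr$tumor_present), logical(1))

.check_balanced <- function(trials, n_trials = 40L, where = "participant") {
  truth <- .trial_truth(trials)
  if (length(trials) != n_trials || sum(truth) != n_trials / 2)
    palp_stop(sprintf("the protocol needs %d trials per %s, half of each class (got %d trials, %d tumor-present)",
                      n_trials, where, length(trials), sum(truth)),
              "palp_protocol_error")
  truth
}

#' Split plan for the within-participant 4-fold protocol
#'
#' One participant's 40 trials (20 per class) are partitioned into four
#' class-balanced folds of ten trials. Each fold in turn is the detection
#' test set (dataset #1); the remaining 30 trials are randomly split —
#' independently `n_reps` times — into 20 training trials (10 per class,
#' dataset #2-1) and 10 criterion-calibration trials (5 per class, dataset
#' #2-2).
#'
#' @param trials List of 40 balanced `trial_record`s.
#' @param n_reps Random repetitions of the #2 split per fold (default 5).
#' @param fold_seed Optional seed for the fold partition only.
#' @param split_seed Optional seed for the repeated #2 splits (set after the
#'   folds so the partition is unchanged across split seeds).
#' @return Nested list (class `validation_plan`, attribute `type =
#'   "within"`): `plan[[fold]][[rep]]` with integer index sets `test`,
#'   `train`, `calibrate`, pairwise disjoint.
#' @export
within_participant_plan <- function(trials, n_reps = 5, fold_seed = NULL,
                                    split_seed = NULL) {
  truth <- .check_balanced(trials)
  if (!is.null(fold_seed)) set.seed(fold_seed)
  pres <- sample(which(truth))
  abs_ <- sample(which(!truth))
  folds <- lapply(1:4, function(k) c(pres[(5 * k - 4):(5 * k)],
                                     abs_[(5 * k - 4):(5 * k)]))
  if (!is.null(split_seed)) set.seed(split_seed)
  plans <- lapply(1:4, function(k) {
    test <- sort(folds[[k]])
    rest_p <- setdiff(which(truth), test)
    rest_a <- setdiff(which(!truth), test)
    lapply(seq_len(n_reps), function(r) {
      tr_p <- sample(rest_p, 10L)
      tr_a <- sample(rest_a, 10L)
      list(fold = k, rep = r, test = test,
           train = sort(c(tr_p, tr_a)),
           calibrate = sort(c(setdiff(rest_p, tr_p), setdiff(rest_a, tr_a))))
    })
  })
  structure(plans, class = "validation_plan", type = "within")
}

#' Split plan for the across-participant leave-one-out protocol
#'
#' Each participant in turn is fully held out as the detection test set
#' (their 40 trials, dataset #1). From every one of the remaining
#' participants, 26 trials (13 per class) go to training (dataset #2-1) and
#' the other 14 (7 per class) to criterion calibration (dataset #2-2); the
#' random selection is repeated `n_reps` times. Trial indices are global
#' positions in the flattened cohort (`(p - 1) * 40 + i`).
#'
#' @param cohort A [generate_cohort()] result or list of per-participant
#'   trial lists, each with 40 balanced trials.
#' @param n_reps Random repetitions per held-out participant (default 5).
#' @param seed Optional seed.
#' @return Nested list (class `validation_plan`, `type = "across"`):
#'   `plan[[participant]][[rep]]` with `held_out`, `test` (40 ids), `train`
#'   (286 ids for 12 participants) and `calibrate` (154 ids).
#' @export
across_participant_plan <- function(cohort, n_reps = 5, seed = NULL) {
  n_p <- length(cohort)
  if (n_p < 2)
    palp_stop("at least two participants are required", "palp_protocol_error")
  truths <- lapply(seq_len(n_p), function(p)
    .check_balanced(cohort[[p]], where = sprintf("participant %d", p)))
  n_t <- length(cohort[[1L]])
  gid <- function(p, i) (p - 1L) * n_t + i
  if (!is.null(seed)) set.seed(seed)
  plans <- lapply(seq_len(n_p), function(p) {
    lapply(seq_len(n_reps), function(r) {
      train <- integer(0)
      cal <- integer(0)
      for (q in setdiff(seq_len(n_p), p)) {
        pres <- which(truths[[q]])
        abs_ <- which(!truths[[q]])
        tr_p <- sample(pres, 13L)
        tr_a <- sample(abs_, 13L)
        train <- c(train, gid(q, c(tr_p, tr_a)))
        cal <- c(cal, gid(q, c(setdiff(pres, tr_p), setdiff(abs_, tr_a))))
      }
      list(held_out = p, rep = r, test = gid(p, seq_len(n_t)),
           train = sort(train), calibrate = sort(cal))
    })
  })
  structure(plans, class = "validation_plan", type = "across")
}

# shared per-unit worker: five (or n_reps) trainings on dataset #2-1, a
# criterion from dataset #2-2 each, the mean criterion applied to dataset #1
# scored by the model ensemble; returns accuracy, ROC area and the scores
.run_unit <- function(trials, reps, cfg, arch, control, ensemble,
                      use_true_segments, window_cache) {
  truth <- .trial_truth(trials)
  ws <- function(i) {
    if (is.null(window_cache[[i]]))
      window_cache[[i]] <- extract_windows(trials[[i]], cfg)
    window_cache[[i]]
  }
  models <- vector("list", length(reps))
  cths <- numeric(length(reps))
  for (r in seq_along(reps)) {
    plan <- reps[[r]]
    xtr <- do.call(rbind, lapply(plan$train, function(i) ws(i)$x))
    ttr <- do.call(rbind, lapply(plan$train, function(i) ws(i)$t))
    fit <- dnn_segmenter(xtr, ttr, arch = arch, control = control)
    cal_scores <- vapply(plan$calibrate, function(i)
      score_trial(fit, trials[[i]], cfg, use_true_segments = use_true_segments,
                  windows = ws(i))$representative, numeric(1))
    cths[r] <- threshold_criterion(
      acc_curve(cal_scores, truth[plan$calibrate]))$c_th
    models[[r]] <- fit
  }
  scorers <- if (ensemble == "average") models else models[length(models)]
  test <- reps[[1L]]$test
  test_scores <- vapply(test, function(i)
    score_trial(scorers, trials[[i]], cfg, use_true_segments = use_true_segments,
                windows = ws(i))$representative, numeric(1))
  mean_cth <- mean(cths)
  roc <- roc_curve(test_scores, truth[test])
  list(mean_criterion = mean_cth,
       accuracy = mean(decide(test_scores, mean_cth) == truth[test]),
       auc = roc$auc, scores = test_scores, truth = truth[test],
       criteria = cths)
}

.new_cache <- function(n) {
  e <- new.env(parent = emptyenv())
  e$x <- vector("list", n)
  structure(e, class = "window_cache")
}
`[[.window_cache` <- function(e, i) e$x[[i]]
`[[<-.window_cache` <- function(e, i, value) { e$x[[i]] <- value; e }

#' Within-participant cross-validation of the full pipeline
#'
#' Runs the 4-fold within-participant protocol for every participant:
#' per fold, `n_reps` networks are trained on dataset #2-1, a detection
#' criterion is calibrated on dataset #2-2 from each, and their mean is
#' applied to dataset #1 scored by the ensemble mean of the repetition
#' models (`ensemble = "last"` scores with the final model only). Fully
#' reproducible from `seed`; the per-repetition trainings draw from the
#' sequential RNG stream, so leave `control$seed` unset.
#'
#' @param x A cohort (list of per-participant trial lists) or a single
#'   participant's list of 40 trials.
#' @param cfg An [extraction_config()] matching the trials' sampling rate.
#' @param control A [dnn_control()]; its `seed` should be `NULL` here.
#' @param arch Optional [dnn_architecture()]; default derives hidden layers
#'   twice the window width.
#' @param n_reps Repetitions of the dataset #2 split per fold.
#' @param seed Seed for the whole run.
#' @param ensemble `"average"` (default) or `"last"`.
#' @param use_true_segments Score within simulator ground-truth stroke
#'   segments instead of force-detected scanning segments.
#' @return Object of class `palp_validation` with a per-fold `results`
#'   data frame (participant, fold, mean_criterion, accuracy, auc) and a
#'   `summary` list of means and SDs.
#' @export
validate_within <- function(x, cfg, control = dnn_control(), arch = NULL,
                            n_reps = 5, seed = NULL,
                            ensemble = c("average", "last"),
                            use_true_segments = FALSE) {
  ensemble <- match.arg(ensemble)
  participants <- if (inherits(x, "palp_cohort") ||
                      (is.list(x) && length(x) && is.list(x[[1L]]) &&
                       is.null(x[[1L]]$tumor_present))) x else list(x)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  decisions_correct <- 0L
  decisions_total <- 0L
  for (p in seq_along(participants)) {
    trials <- participants[[p]]
    plan <- within_participant_plan(trials, n_reps = n_reps)
    cache <- .new_cache(length(trials))
    for (k in seq_along(plan)) {
      unit <- .run_unit(trials, plan[[k]], cfg, arch, control, ensemble,
                        use_true_segments, cache)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = attr(trials, "participant_id") %||% sprintf("P%02d", p),
        fold = k, mean_criterion = unit$mean_criterion,
        accuracy = unit$accuracy, auc = unit$auc)
      decisions_correct <- decisions_correct +
        round(unit$accuracy * length(unit$scores))
      decisions_total <- decisions_total + length(unit$scores)
    }
  }
  res <- do.call(rbind, rows)
  structure(list(type = "within", results = res,
                 summary = .validation_summary(res),
                 decisions = c(correct = decisions_correct,
                               total = decisions_total)),
            class = "palp_validation")
}

#' Across-participant (leave-one-out) cross-validation
#'
#' Runs the leave-one-participant-out protocol over the cohort; see
#' [validate_within()] for the shared training/calibration/scoring
#' mechanics and arguments.
#'
#' @inheritParams validate_within
#' @param cohort List of per-participant trial lists (each 40 balanced
#'   trials).
#' @return Object of class `palp_validation`; one results row per held-out
#'   participant.
#' @export
validate_across <- function(cohort, cfg, control = dnn_control(), arch = NULL,
                            n_reps = 5, seed = NULL,
                            ensemble = c("average", "last"),
                            use_true_segments = FALSE) {
  ensemble <- match.arg(ensemble)
  if (!is.null(seed)) set.seed(seed)
  flat <- do.call(c, lapply(cohort, unclass))
  plan <- across_participant_plan(cohort, n_reps = n_reps)
  cache <- .new_cache(length(flat))
  rows <- list()
  decisions_correct <- 0L
  decisions_total <- 0L
  for (p in seq_along(plan)) {
    unit <- .run_unit(flat, plan[[p]], cfg, arch, control, ensemble,
                      use_true_segments, cache)
    rows[[p]] <- data.frame(
      participant = attr(cohort[[p]], "participant_id") %||% sprintf("P%02d", p),
      fold = p, mean_criterion = unit$mean_criterion,
      accuracy = unit$accuracy, auc = unit$auc)
    decisions_correct <- decisions_correct +
      round(unit$accuracy * length(unit$scores))
    decisions_total <- decisions_total + length(unit$scores)
  }
  res <- do.call(rbind, rows)
  structure(list(type = "across", results = res,
                 summary = .validation_summary(res),
                 decisions = c(correct = decisions_correct,
                               total = decisions_total)),
            class = "palp_validation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validation_summary <- function(res) {
  list(mean_accuracy = mean(res$accuracy), sd_accuracy = sd(res$accuracy),
       mean_auc = mean(res$auc), sd_auc = sd(res$auc),
       mean_criterion = mean(res$mean_criterion),
       sd_criterion = sd(res$mean_criterion))
}

#' @export
print.palp_validation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s-participant validation: %d unit(s)\n",
              if (x$type == "within") "Within" else "Across", nrow(x$results)))
  cat(sprintf("  ACC  = %.3f +/- %.3f\n", s$mean_accuracy, s$sd_accuracy))
  cat(sprintf("  A_g  = %.3f +/- %.3f\n", s$mean_auc, s$sd_auc))
  cat(sprintf("  c_th = %.3f +/- %.3f\n", s$mean_criterion, s$sd_criterion))
  invisible(x)
}

#' @export
summary.palp_validation <- function(object, ...) {
  cat(sprintf("%s-participant validation, per-unit results:\n",
              if (object$type == "within") "Within" else "Across"))
  print(object$results, row.names = FALSE)
  print(object)
  invisible(object$summary)
}

#' Compare model performance with human performance
#'
#' A thin hook around the standard paired Wilcoxon signed-rank test for
#' comparing per-participant model accuracies (or ROC areas) with values
#' recorded for human participants; a Shapiro-Wilk normality check on the
#' paired differences is reported alongside. Supply your own human values —
#' the package does not ship any.
#'
#' @param model_values Per-participant model metric.
#' @param human_values Per-participant human metric, same length and order.
#' @param ... Passed on to [stats::wilcox.test()].
#' @return List with the `wilcoxon` and `shapiro` htest objects.
#' @export
compare_with_human <- function(model_values, human_values, ...) {
  if (length(model_values) != length(human_values))
    palp_stop("model and human values must be paired (equal length)",
              "palp_shape_error")
  d <- model_values - human_values
  list(shapiro = shapiro.test(d),
       wilcoxon = wilcox.test(model_values, human_values, paired = TRUE, ...))
}
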