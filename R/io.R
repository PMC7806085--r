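## Trial container: one versioned delimited-text file per trial.
## Header lines start with "# " and carry key=value metadata
## (participant_id, trial_index, tumor_present, sampling_rate, the stroke
## ground truth and the generator profile when known), followed by a
## tab-separated table with columns time_s, sensor, tangential_force,
## tumor_label and optionally sensor_clean. Numbers are written with 17
## significant digits so doubles round-trip exactly.

.fmt <- function(x) sprintf("%.17g", x)

.seg_encode <- function(segs) {
  if (is.null(segs) || nrow(segs) == 0L) return("")
  paste(sprintf("%d:%d", segs[, 1L], segs[, 2L]), collapse = ";")
}

.seg_decode <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

.profile_encode <- function(p) {
  if (is.null(p)) return("")
  paste(sprintf("%s:%s", names(unclass(p)),
                vapply(unclass(p), .fmt, character(1))), collapse = ";")
}

.profile_decode <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  vals <- lapply(kv, function(x) as.numeric(x[2L]))
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  do.call(scan_profile, vals)
}

#' Write trials to a directory of delimited text files
#'
#' Serializes each trial to `<participant>_trial<index>.tsv` (versioned
#' header plus a tab-separated time series) and writes a `manifest.tsv`
#' listing all files with their ground truth. The format round-trips
#' exactly through [read_trials()].
#'
#' @param trials A list of `trial_record`s or a [generate_cohort()] result.
#' @param path Directory to create/fill.
#' @return Invisibly, the written trial file paths.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "palp_cohort")) trials <- do.call(c, lapply(trials, unclass))
  if (inherits(trials, "trial_record")) trials <- list(trials)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    f <- file.path(path, sprintf("%s_trial%03d.tsv", tr$participant_id,
                                 tr$trial_index))
    hdr <- c("# palpassist_trial v1",
             sprintf("# participant_id=%s", tr$participant_id),
             sprintf("# trial_index=%d", tr$trial_index),
             sprintf("# tumor_present=%s", tr$tumor_present),
             sprintf("# sampling_rate=%s", .fmt(tr$sampling_rate)),
             sprintf("# true_segments=%s", .seg_encode(tr$true_segments)),
             sprintf("# profile=%s", .profile_encode(tr$profile)))
    L <- length(tr$sensor)
    tab <- data.frame(time_s = .fmt((seq_len(L) - 1) / tr$sampling_rate),
                      sensor = .fmt(tr$sensor),
                      tangential_force = .fmt(tr$tangential_force),
                      tumor_label = tr$tumor_label)
    if (!is.null(tr$clean)) tab$sensor_clean <- .fmt(tr$clean)
    con <- file(f, "w")
    writeLines(hdr, con)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    files[i] <- f
  }
  manifest <- data.frame(
    file = basename(files),
    participant_id = vapply(trials, `[[`, character(1), "participant_id"),
    trial_index = vapply(trials, `[[`, integer(1), "trial_index"),
    tumor_present = vapply(trials, `[[`, logical(1), "tumor_present"))
  write.table(manifest, file.path(path, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(files)
}

.read_trial_file <- function(f) {
  lines <- readLines(f, n = 64L)
  hdr_n <- sum(startsWith(lines, "#"))
  if (hdr_n == 0L || !grepl("^# palpassist_trial v1", lines[1L]))
    palp_stop(sprintf("%s: not a palpassist trial file (unknown schema)", basename(f)),
              "palp_parse_error")
  meta <- list()
  for (l in lines[2:hdr_n]) {
    kv <- sub("^# ", "", l)
    k <- sub("=.*$", "", kv)
    meta[[k]] <- sub("^[^=]*=", "", kv)
  }
  tab <- tryCatch(
    read.table(f, header = TRUE, sep = "\t", comment.char = "#",
               fill = FALSE, colClasses = "numeric"),
    error = function(e) palp_stop(
      sprintf("%s: malformed table (%s)", basename(f), conditionMessage(e)),
      "palp_parse_error"))
  needed <- c("time_s", "sensor", "tangential_force", "tumor_label")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    palp_stop(sprintf("%s: missing column(s) %s", basename(f),
                      paste(missing_cols, collapse = ", ")), "palp_parse_error")
  for (cl in needed) if (anyNA(tab[[cl]]))
    palp_stop(sprintf("%s: column %s is truncated or non-numeric", basename(f), cl),
              "palp_parse_error")
  if (!all(tab$tumor_label %in% c(0, 1)))
    palp_stop(sprintf("%s: column tumor_label must be binary", basename(f)),
              "palp_parse_error")
  sr <- as.numeric(meta$sampling_rate)
  if (is.na(sr) || sr <= 0)
    palp_stop(sprintf("%s: missing or invalid sampling_rate", basename(f)),
              "palp_parse_error")
  if (nrow(tab) > 1 &&
      max(abs(diff(tab$time_s) - 1 / sr)) > 1e-6 / sr)
    palp_stop(sprintf("%s: column time_s does not increase at 1/sampling_rate", basename(f)),
              "palp_parse_error")
  segs <- if (is.null(meta$true_segments)) NULL else .seg_decode(meta$true_segments)
  structure(list(participant_id = meta$participant_id %||% "unknown",
                 trial_index = as.integer(meta$trial_index %||% NA),
                 tumor_present = identical(meta$tumor_present, "TRUE"),
                 sensor = tab$sensor,
                 tumor_label = as.integer(tab$tumor_label),
                 tangential_force = tab$tangential_force,
                 true_segments = segs,
                 clean = tab$sensor_clean,
                 sampling_rate = sr,
                 profile = .profile_decode(meta$profile %||% NA_character_)),
            class = "trial_record")
}

#' Read trials written by [write_trials()]
#'
#' Files with a missing `true_segments` entry load with `NULL` segments
#' (segment-dependent scoring then needs force-detected segments). Parse
#' failures name the offending file and column.
#'
#' @param path Directory containing `*_trial*.tsv` files.
#' @param as_cohort Group the trials by participant into a `palp_cohort`.
#' @return A list of `trial_record`s, or a `palp_cohort` when `as_cohort`.
#' @export
read_trials <- function(path, as_cohort = FALSE) {
  files <- sort(list.files(path, pattern = "_trial[0-9]+\\.tsv$",
                           full.names = TRUE))
  if (!length(files))
    palp_stop(sprintf("no trial files found under %s", path), "palp_parse_error")
  trials <- lapply(files, .read_trial_file)
  if (!as_cohort) return(trials)
  ids <- vapply(trials, `[[`, character(1), "participant_id")
  parts <- lapply(split(trials, factor(ids, levels = unique(ids))), function(x) {
    attr(x, "participant_id") <- x[[1L]]$participant_id
    x
  })
  structure(unname(parts), class = "palp_cohort")
}

#' Save / load a fitted segmenter
#'
#' Model parameters are stored in R's native serialization format together
#' with the architecture, the training-set normalization statistics and the
#' full training control (including its seed), so a loaded model scores
#' identically to the one saved.
#'
#' @param model A [dnn_segmenter()].
#' @param path File path (conventionally `.rds`).
#' @return `write_dnn_segmenter` returns `path` invisibly;
#'   `read_dnn_segmenter` returns the model.
#' @export
write_dnn_segmenter <- function(model, path) {
  if (!inherits(model, "dnn_segmenter"))
    palp_stop("model must be a dnn_segmenter object", "palp_parameter_error")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_dnn_segmenter
#' @export
read_dnn_segmenter <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dnn_segmenter"))
    palp_stop(sprintf("%s does not contain a dnn_segmenter", path),
              "palp_parse_error")
  model
}
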