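#' Morphological feature evaluation
#'
#' Kernels shared by the catalogue: time spans in ms, baseline-corrected
#' amplitudes (the beat baseline is the PPG value at the onset O for PPG-level
#' features; derivative levels oscillate about zero and use no baseline),
#' trapezoidal curve areas in a.u.*s, power areas as raw sums of squared
#' baseline-corrected samples over closed index intervals, slopes in a.u./s,
#' and plain quotients for ratios. A missing landmark propagates as `NA`.
#'
#' @name features
NULL

# Parse a landmark ref like "c-2", "S", "O+1", "O2" into label + shift.
parse_ref <- function(ref) {
  m <- regmatches(ref, regexec("^([A-Za-z]2?)([+-][0-9])?$", ref))[[1L]]
  if (length(m) == 0L) stop_ppght("bad landmark ref '%s'", ref)
  shift <- if (m[3L] == "") 0L else as.integer(m[3L])
  list(label = m[2L], shift = shift)
}

# Landmark time (sample index) from one fiducials row; "O2" = beat end.
ref_time <- function(ref, fid) {
  label <- parse_ref(ref)$label
  t <- if (label == "O2") fid$beat_end else fid[[paste0("t_", label)]]
  if (is.null(t) || is.na(t)) NA_integer_ else as.integer(t)
}

# Baseline-corrected value of a ref on its (shifted) level.
ref_value <- function(ref, wave, fid) {
  p <- parse_ref(ref)
  t <- ref_time(ref, fid)
  if (is.na(t)) return(NA_real_)
  lvl <- LANDMARK_LEVEL[[p$label]] + p$shift
  v <- project(wave, t, LANDMARK_LEVEL[[p$label]], p$shift)
  if (lvl == 0L) v - beat_baseline(wave, fid) else v
}

beat_baseline <- function(wave, fid) wave$ppg[fid$t_O]

eval_span <- function(args, wave, fid) {
  t1 <- ref_time(args$from, fid); t2 <- ref_time(args$to, fid)
  if (is.na(t1) || is.na(t2)) return(NA_real_)
  (t2 - t1) / wave$fs * 1000
}

eval_amp <- function(args, wave, fid) ref_value(args$ref, wave, fid)

eval_area <- function(args, wave, fid) {
  t1 <- ref_time(args$from, fid); t2 <- ref_time(args$to, fid)
  if (is.na(t1) || is.na(t2) || t2 < t1) return(NA_real_)
  y <- wave$ppg[t1:t2] - beat_baseline(wave, fid)
  trapz(y, dx = 1 / wave$fs)
}

eval_pow <- function(args, wave, fid) {
  t1 <- ref_time(args$t1, fid); t2 <- ref_time(args$t2, fid)
  if (is.na(t1) || is.na(t2) || t2 < t1) return(NA_real_)
  lvl <- as.integer(args$level)
  y <- wave_level(wave, lvl)[t1:t2]
  if (lvl == 0L) y <- y - beat_baseline(wave, fid)
  sum(y^2)
}

eval_slope <- function(args, wave, fid) {
  t1 <- ref_time(args$from, fid); t2 <- ref_time(args$to, fid)
  if (is.na(t1) || is.na(t2) || t1 == t2) return(NA_real_)
  v1 <- ref_value(args$from, wave, fid); v2 <- ref_value(args$to, wave, fid)
  (v2 - v1) / ((t2 - t1) / wave$fs)
}

eval_comb <- function(args, wave, fid) {
  num_labels <- unlist(args$num)
  vals <- vapply(num_labels, ref_value, 0, wave = wave, fid = fid)
  den <- ref_value(args$den, wave, fid)
  if (anyNA(vals) || is.na(den) || den == 0) return(NA_real_)
  (vals[1L] - sum(vals[-1L])) / den
}

#' Evaluate the full catalogue on one beat
#'
#' Non-ratio kernels are evaluated first; ratio entries then divide the
#' already-computed operands, so a zero or missing denominator yields `NA`.
#'
#' @param wave A `waveform_set`.
#' @param fid One-row slice of [delineate()] output.
#' @param cat_list Catalogue (defaults to [ppg_catalogue()]).
#' @return Named numeric vector, one value per catalogue entry.
#' @export
evaluate_beat <- function(wave, fid, cat_list = ppg_catalogue()) {
  vals <- stats::setNames(rep(NA_real_, length(cat_list)),
                          vapply(cat_list, `[[`, "", "name"))
  ratios <- list()
  for (entry in cat_list) {
    k <- entry$kernel
    if (k == "ratio") { ratios[[entry$name]] <- entry$args; next }
    vals[[entry$name]] <- switch(k,
      span = eval_span(entry$args, wave, fid),
      amp = eval_amp(entry$args, wave, fid),
      area = eval_area(entry$args, wave, fid),
      pow = eval_pow(entry$args, wave, fid),
      slope = eval_slope(entry$args, wave, fid),
      comb = eval_comb(entry$args, wave, fid),
      stop_ppght("unknown kernel '%s'", k))
  }
  for (nm in names(ratios)) {
    a <- ratios[[nm]]
    num <- vals[[a$num]]; den <- vals[[a$den]]
    vals[[nm]] <- if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  }
  vals
}

#' Extract one subject's feature vector from a record
#'
#' Evaluates the catalogue on every complete beat and aggregates across beats
#' by the median (missing values excluded per feature). A record with no
#' complete beats yields an all-`NA` vector with a warning.
#'
#' @param wave A `waveform_set`.
#' @param fids Output of [delineate()]; computed if omitted.
#' @param cat_list Catalogue.
#' @return Named numeric vector of length `length(cat_list)`.
#' @export
extract_features <- function(wave, fids = NULL, cat_list = ppg_catalogue()) {
  if (is.null(fids)) fids <- delineate(wave)
  if (nrow(fids) == 0L) {
    warning("no complete beats: all features missing", call. = FALSE)
    return(stats::setNames(rep(NA_real_, length(cat_list)),
                           vapply(cat_list, `[[`, "", "name")))
  }
  per_beat <- vapply(seq_len(nrow(fids)),
                     function(i) evaluate_beat(wave, fids[i, ], cat_list),
                     numeric(length(cat_list)))
  apply(matrix(per_beat, nrow = length(cat_list)), 1L, stats::median, na.rm = TRUE) |>
    stats::setNames(vapply(cat_list, `[[`, "", "name"))
}

#' Build the cohort feature table
#'
#' For each subject: pick the best of their records by skewness SQI, filter,
#' differentiate, delineate, evaluate the catalogue, and aggregate. The
#' result has the metadata columns first (`subject_id, sbp, dbp, bp_class`)
#' followed by the feature columns.
#'
#' @param records List of `raw_record`s (three per subject typically).
#' @param meta Metadata data.frame with `subject_id`, `sbp`, `dbp` (and
#'   optionally `bp_class`, recomputed if absent).
#' @param fs Sampling rate; defaults to each record's own.
#' @param filter_args Named list passed to [bandpass_filter()].
#' @return Data frame of class `feature_table`.
#' @export
extract_cohort_features <- function(records, meta, fs = NULL, filter_args = list()) {
  ids <- vapply(records, `[[`, "", "subject_id")
  cat_list <- ppg_catalogue()
  rows <- lapply(meta$subject_id, function(sid) {
    recs <- records[ids == sid]
    if (length(recs) == 0L) return(rep(NA_real_, length(cat_list)))
    best <- recs[[select_best_record(recs)$selected]]
    ws <- do.call(waveform_set,
                  c(list(samples = best$samples, fs = fs %||% best$fs), filter_args))
    extract_features(ws, cat_list = cat_list)
  })
  feats <- do.call(rbind, rows)
  bp_class <- if ("bp_class" %in% names(meta)) meta$bp_class else
    as.character(assign_bp_class(meta$sbp, meta$dbp))
  out <- cbind(data.frame(subject_id = meta$subject_id, sbp = meta$sbp,
                          dbp = meta$dbp, bp_class = bp_class,
                          stringsAsFactors = FALSE),
               as.data.frame(feats))
  class(out) <- c("feature_table", class(out))
  out
}

#' Names of the feature columns of a feature table
#' @param table A feature table.
#' @return Character vector.
#' @export
feature_columns <- function(table) setdiff(names(table), META_COLS)

#' Z-score normalize a feature table
#'
#' Per-column z-score over non-missing entries using the sample (n-1)
#' standard deviation; the fitted centers and scales are attached so they can
#' be reused on held-out data. Zero-variance columns are set to all zeros
#' with a warning.
#'
#' @param table A feature table.
#' @param center,scale Optional previously fitted statistics (named vectors).
#' @return Normalized table with attributes `center` and `scale`.
#' @export
normalize_features <- function(table, center = NULL, scale = NULL) {
  fc <- feature_columns(table)
  if (nrow(table) < 2L && is.null(center)) stop_ppght("need >= 2 subjects to fit")
  if (is.null(center)) {
    center <- vapply(table[fc], function(x) mean(x, na.rm = TRUE), 0)
    scale <- vapply(table[fc], function(x) stats::sd(x, na.rm = TRUE), 0)
  }
  zero <- !is.na(scale) & scale == 0
  if (any(zero))
    warning(sprintf("%d zero-variance feature(s) left as zeros", sum(zero)), call. = FALSE)
  for (j in seq_along(fc)) {
    x <- table[[fc[j]]] - center[j]
    table[[fc[j]]] <- if (zero[j]) 0 * x else x / scale[j]
  }
  attr(table, "center") <- center
  attr(table, "scale") <- scale
  table
}
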