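#' Readers, writers, configuration and end-to-end orchestration
#'
#' Records travel as plain-text files, one integer sample per line, named
#' `<subject>_<k>.txt` (k = 0, 1, 2), next to a `meta.csv` with columns
#' `subject_id, age, sex, height_cm, weight_kg, sbp, dbp`. This mirrors the
#' layout of openly deposited short-record PPG datasets, so the pipeline runs
#' unchanged on real downloads and on synthetic cohorts.
#'
#' @name pipeline_io
NULL

#' Write a cohort to a signal directory
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$records) {
    path <- file.path(dir, sprintf("%s_%d.txt", rec$subject_id, rec$record_index))
    writeLines(as.character(rec$samples), path)
  }
  meta <- cohort$meta[c("subject_id", "age", "sex", "height_cm", "weight_kg",
                        "sbp", "dbp")]
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a signal directory
#'
#' Parses every `<subject>_<k>.txt` file (one sample per line; blank trailing
#' lines ignored; single-column CSV also accepted). Unparseable files are
#' skipped with a warning. Subjects are ordered by file name for stability.
#'
#' @param path Directory.
#' @param fs Sampling rate to attach (default 1000).
#' @return List of `raw_record`.
#' @export
read_signal_dir <- function(path, fs = 1000) {
  if (!dir.exists(path)) stop_ppght("no such directory: %s", path)
  files <- sort(list.files(path, pattern = "^.+_[0-9]+\\.(txt|csv)$", full.names = TRUE))
  records <- list()
  for (f in files) {
    base <- sub("\\.(txt|csv)$", "", basename(f))
    m <- regmatches(base, regexec("^(.*)_([0-9]+)$", base))[[1L]]
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    samples <- suppressWarnings(as.numeric(lines))
    if (length(samples) == 0L || anyNA(samples)) {
      warning(sprintf("skipping unparseable file %s", basename(f)), call. = FALSE)
      next
    }
    records[[length(records) + 1L]] <- structure(
      list(subject_id = m[2L], record_index = as.integer(m[3L]),
           samples = samples, fs = fs),
      class = "raw_record")
  }
  if (length(records) == 0L) stop_ppght("no parseable record files in %s", path)
  records
}

#' Read a subject metadata CSV
#' @param path CSV path with at least `subject_id, sbp, dbp`.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sbp", "dbp")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop_ppght("metadata lacks column(s): %s", paste(missing_cols, collapse = ", "))
  meta
}

config_defaults <- function() list(
  fs = 1000, band_low = 0.5, band_high = 10, filter_order = 4, filter_rs = 20,
  duration = 2.1, n_bins = 10L, k_neighbors = 10L, k = 10L, knn_k = 10L,
  nfolds = 10L, seed = 17L, effect = 1,
  n_norm = 48L, n_pre = 41L, n_hyp = 35L,
  methods = SELECTION_METHODS, classifiers = CLASSIFIERS,
  global_selection = FALSE
)

#' Validate and resolve a run configuration
#'
#' Fills defaults (all of which equal the stated acquisition/analysis values
#' where one exists: fs = 1000 Hz, band 0.5--10 Hz, design order 4, K = 10
#' neighbours, top-10 subset, 10 folds), checks ranges, and returns the fully
#' resolved configuration. Re-validating a resolved configuration is a no-op.
#'
#' @param cfg Named list (possibly empty or partial).
#' @return Resolved config of class `ppg_config`.
#' @export
validate_config <- function(cfg = list()) {
  unknown <- setdiff(names(cfg), names(config_defaults()))
  if (length(unknown))
    stop_ppght("unknown config field(s): %s", paste(unknown, collapse = ", "))
  out <- utils::modifyList(config_defaults(), cfg)
  problems <- character(0)
  if (out$fs <= 20) problems <- c(problems, "fs must exceed 20 Hz")
  if (out$band_low <= 0 || out$band_high <= out$band_low)
    problems <- c(problems, "band edges must satisfy 0 < low < high")
  if (out$band_high >= out$fs / 2) problems <- c(problems, "band_high above Nyquist")
  if (out$nfolds < 2) problems <- c(problems, "nfolds must be >= 2")
  if (out$k < 1) problems <- c(problems, "k must be >= 1")
  if (out$n_bins < 2) problems <- c(problems, "n_bins must be >= 2")
  if (!all(out$methods %in% SELECTION_METHODS))
    problems <- c(problems, "unknown selection method")
  if (!all(out$classifiers %in% CLASSIFIERS))
    problems <- c(problems, "unknown classifier")
  if (length(problems))
    stop_ppght("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  class(out) <- c("ppg_config", class(out))
  out
}

#' Run the whole pipeline on a synthetic or on-disk cohort
#'
#' simulate (or read) -> quality-select & filter -> delineate -> extract the
#' 125 features -> rank -> cross-validated classification. All randomness
#' flows from `cfg$seed`.
#'
#' @param cfg Config list (see [validate_config()]).
#' @param signal_dir Optional directory of records + `meta.csv`; when NULL a
#'   synthetic cohort is generated from the config's class counts.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return List with `features` (feature table) and `report`
#'   (`stratification_report`).
#' @export
run_pipeline <- function(cfg = list(), signal_dir = NULL, out_dir = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(signal_dir)) {
    cohort <- generate_cohort(cfg$n_norm, cfg$n_pre, cfg$n_hyp, seed = cfg$seed,
                              duration = cfg$duration, fs = cfg$fs,
                              effect = cfg$effect)
    records <- cohort$records
    meta <- cohort$meta
  } else {
    records <- read_signal_dir(signal_dir, fs = cfg$fs)
    meta <- read_metadata(file.path(signal_dir, "meta.csv"))
  }
  features <- extract_cohort_features(
    records, meta,
    filter_args = list(low = cfg$band_low, high = cfg$band_high,
                       order = cfg$filter_order, rs = cfg$filter_rs))
  report <- run_experiment(features, methods = cfg$methods,
                           classifiers = cfg$classifiers, k = cfg$k,
                           nfolds = cfg$nfolds, seed = cfg$seed,
                           n_bins = cfg$n_bins, k_neighbors = cfg$k_neighbors,
                           global_selection = cfg$global_selection)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(features = features, report = report)
}
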