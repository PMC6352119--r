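#' Blood-pressure class assignment
#'
#' Applies the standard screening criteria: hypertensive if SBP >= 140 or
#' DBP >= 90; otherwise prehypertensive if SBP >= 120 or DBP >= 80; otherwise
#' normotensive. Evaluating the hypertensive rule first resolves the printed
#' boundary overlap at 140/90 mmHg.
#'
#' @param sbp,dbp Numeric vectors, mmHg (SBP in 40--300, DBP in 20--200).
#' @return Factor with levels normotensive/prehypertensive/hypertensive.
#' @export
assign_bp_class <- function(sbp, dbp) {
  if (any(is.na(sbp) | is.na(dbp))) stop_ppght("missing blood-pressure values")
  if (any(sbp < 40 | sbp > 300)) stop_ppght("SBP outside physiologic range 40-300 mmHg")
  if (any(dbp < 20 | dbp > 200)) stop_ppght("DBP outside physiologic range 20-200 mmHg")
  cls <- ifelse(sbp >= 140 | dbp >= 90, "hypertensive",
         ifelse(sbp >= 120 | dbp >= 80, "prehypertensive", "normotensive"))
  factor(cls, levels = BP_CLASSES)
}

#' Subset a feature table for a pairwise comparison
#'
#' The positive class is always the higher-blood-pressure group, so
#' sensitivity reads as sensitivity to disease.
#'
#' @param table Feature table with a `bp_class` column.
#' @param pairing One of `"norm_vs_pre"`, `"norm_vs_hyp"`, `"normpre_vs_hyp"`.
#' @return List with `table` (subset rows) and `labels` (factor, negative
#'   level first).
#' @export
pairing_split <- function(table, pairing) {
  cls <- as.character(table$bp_class)
  keep_pos <- switch(pairing,
    norm_vs_pre = cls == "prehypertensive",
    norm_vs_hyp = cls == "hypertensive",
    normpre_vs_hyp = cls == "hypertensive",
    stop_ppght("unknown pairing '%s'", pairing))
  keep_neg <- switch(pairing,
    norm_vs_pre = cls == "normotensive",
    norm_vs_hyp = cls == "normotensive",
    normpre_vs_hyp = cls %in% c("normotensive", "prehypertensive"))
  keep <- keep_pos | keep_neg
  labels <- factor(ifelse(keep_pos[keep], "pos", "neg"), levels = c("neg", "pos"))
  list(table = table[keep, , drop = FALSE], labels = labels)
}

#' F1 score from positive predictivity and sensitivity
#'
#' Harmonic mean of precision (PP) and recall (SE), on the percent scale.
#'
#' @param pp,se Percentages.
#' @return F1 in percent (`NA` if `pp + se == 0`).
#' @export
f1_score <- function(pp, se) ifelse(pp + se > 0, 2 * pp * se / (pp + se), NA_real_)

confusion_metrics <- function(tp, fp, fn, tn) {
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  pp <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  list(TP = tp, FP = fp, FN = fn, TN = tn, PP = pp, SE = se, F1 = f1_score(pp, se))
}

# Stratified fold assignment: a seeded shuffle within each class, dealt
# round-robin. Returns an integer fold id per row.
stratified_fold_ids <- function(labels, nfolds, seed = 17L) {
  n <- length(labels)
  min_class <- min(table(labels))
  if (min_class < nfolds) {
    warning(sprintf("fold count reduced to %d (minority class size)", min_class),
            call. = FALSE)
    nfolds <- min_class
  }
  set.seed(seed)
  ids <- integer(n)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    ids[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  ids
}

# Fold-wise preprocessing: median-impute from the training rows, then z-score
# with training statistics.
fold_prepare <- function(X_train, X_test) {
  for (j in seq_len(ncol(X_train))) {
    med <- stats::median(X_train[, j], na.rm = TRUE)
    if (is.na(med)) med <- 0
    X_train[is.na(X_train[, j]), j] <- med
    X_test[is.na(X_test[, j]), j] <- med
  }
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(X_train, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(X_test, 2L, mu), 2L, sdv, "/"))
}

#' Stratified 10-fold cross-validated stratification experiment
#'
#' Runs one (pairing, selection method, classifier) cell: folds are stratified
#' by class with a seeded shuffle; imputation, z-scoring and feature selection
#' are refit inside every training fold (no leakage; set
#' `global_selection = TRUE` to emulate a single whole-cohort selection);
#' confusion counts are pooled over folds.
#'
#' @param table Feature table.
#' @param pairing Pairing name (see [pairing_split()]).
#' @param method Selection method (see [rank_features()]).
#' @param classifier Classifier name (see [fit_predict()]).
#' @param k Feature subset size (default 10).
#' @param nfolds Number of folds (default 10).
#' @param seed Fold-shuffle seed (default 17).
#' @param n_bins,k_neighbors Selection parameters.
#' @param global_selection Rank once on the full pairing table instead of per
#'   fold.
#' @return One-row data.frame with confusion counts and PP/SE/F1 (percent).
#' @export
stratified_10fold <- function(table, pairing, method, classifier, k = 10L,
                              nfolds = 10L, seed = 17L, n_bins = 10L,
                              k_neighbors = 10L, global_selection = FALSE) {
  sp <- pairing_split(table, pairing)
  run_cv_cell(sp$table, sp$labels, method, classifier, k, nfolds, seed,
              n_bins, k_neighbors, global_selection,
              extra = list(pairing = pairing))
}

run_cv_cell <- function(tab, labels, method, classifier, k, nfolds, seed,
                        n_bins, k_neighbors, global_selection, extra = list()) {
  folds <- stratified_fold_ids(labels, nfolds, seed)
  X <- feature_matrix(tab)
  keep <- colnames(X)
  global_rank <- if (global_selection)
    top_k(rank_features(tab, labels, method, n_bins, k_neighbors, k = k), k)
  tp <- fp <- fn <- tn <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    sel <- if (global_selection) global_rank else
      top_k(rank_features(tab[tr, , drop = FALSE], labels[tr], method,
                          n_bins, k_neighbors, k = k), k)
    prep <- fold_prepare(X[tr, sel, drop = FALSE], X[te, sel, drop = FALSE])
    pred <- fit_predict(classifier, prep$train, labels[tr], prep$test)
    truth <- labels[te]
    tp <- tp + sum(pred == "pos" & truth == "pos")
    fp <- fp + sum(pred == "pos" & truth == "neg")
    fn <- fn + sum(pred == "neg" & truth == "pos")
    tn <- tn + sum(pred == "neg" & truth == "neg")
  }
  cbind(data.frame(pairing = extra$pairing %||% NA_character_,
                   method = method, classifier = classifier,
                   stringsAsFactors = FALSE),
        as.data.frame(confusion_metrics(tp, fp, fn, tn)))
}

#' Full stratification experiment grid
#'
#' Runs every (pairing x selection method x classifier) cell and flags the
#' highest-F1 cell per pairing. To avoid re-ranking per classifier, rankings
#' are computed once per (pairing, fold, method) and shared across the four
#' classifiers.
#'
#' @param table Feature table with all three classes.
#' @param methods Selection methods (default: all six).
#' @param classifiers Classifier names (default: all four).
#' @inheritParams stratified_10fold
#' @return Data frame of class `stratification_report`, one row per cell,
#'   with a logical `best` column.
#' @export
run_experiment <- function(table, methods = SELECTION_METHODS,
                           classifiers = CLASSIFIERS, k = 10L, nfolds = 10L,
                           seed = 17L, n_bins = 10L, k_neighbors = 10L,
                           global_selection = FALSE) {
  if (nlevels(factor(table$bp_class)) < 3L)
    stop_ppght("table must contain all three blood-pressure classes")
  rows <- list()
  for (pairing in PAIRINGS) {
    sp <- pairing_split(table, pairing)
    tab <- sp$table; labels <- sp$labels
    folds <- stratified_fold_ids(labels, nfolds, seed)
    X <- feature_matrix(tab)
    counts <- array(0L, dim = c(length(methods), length(classifiers), 4L),
                    dimnames = list(methods, classifiers, c("TP", "FP", "FN", "TN")))
    for (f in sort(unique(folds))) {
      tr <- folds != f; te <- !tr
      truth <- labels[te]
      for (m in methods) {
        sel <- if (global_selection)
          top_k(rank_features(tab, labels, m, n_bins, k_neighbors, k = k), k)
        else
          top_k(rank_features(tab[tr, , drop = FALSE], labels[tr], m,
                              n_bins, k_neighbors, k = k), k)
        prep <- fold_prepare(X[tr, sel, drop = FALSE], X[te, sel, drop = FALSE])
        for (cl in classifiers) {
          pred <- fit_predict(cl, prep$train, labels[tr], prep$test)
          counts[m, cl, ] <- counts[m, cl, ] + c(
            sum(pred == "pos" & truth == "pos"),
            sum(pred == "pos" & truth == "neg"),
            sum(pred == "neg" & truth == "pos"),
            sum(pred == "neg" & truth == "neg"))
        }
      }
    }
    for (m in methods) for (cl in classifiers) {
      cm <- confusion_metrics(counts[m, cl, "TP"], counts[m, cl, "FP"],
                              counts[m, cl, "FN"], counts[m, cl, "TN"])
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(pairing = pairing, method = m, classifier = cl,
                         stringsAsFactors = FALSE),
              as.data.frame(cm))
    }
  }
  report <- do.call(rbind, rows)
  report$best <- FALSE
  for (pairing in PAIRINGS) {
    idx <- which(report$pairing == pairing)
    if (length(idx)) report$best[idx[which.max(report$F1[idx])]] <- TRUE
  }
  attr(report, "seed") <- seed
  attr(report, "k") <- k
  class(report) <- c("stratification_report", class(report))
  report
}
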