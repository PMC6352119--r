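#' Filter-type feature ranking
#'
#' Six filter methods rank the catalogue features for a binary class label:
#' absolute Spearman correlation, ReliefF, information gain, the chi-square
#' statistic, greedy mRMR (mutual-information difference scheme) and Gini
#' impurity reduction. The discretization-based scores (info gain, chi-square,
#' mRMR, Gini) use equal-frequency binning (10 bins by default), which makes
#' them invariant to strictly increasing transforms of a feature. Subjects
#' with a missing value are dropped pairwise per feature; ties in the scores
#' are resolved by catalogue order.
#'
#' @name selection
NULL

ranking_result <- function(method, scores, feature_names, ordered = NULL) {
  if (is.null(ordered)) {
    o <- order(-scores, seq_along(scores))
    ordered <- feature_names[o]
    scores <- scores[o]
  }
  structure(list(method = method, ordered_features = ordered,
                 scores = stats::setNames(scores, ordered)),
            class = "ppg_ranking")
}

#' @export
print.ppg_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<ppg_ranking: %s>\n", x$method))
  print(utils::head(x$scores, n))
  invisible(x)
}

#' Take the top-k features of a ranking
#' @param result A `ppg_ranking`.
#' @param k Subset size (default 10).
#' @return Character vector of feature names.
#' @export
top_k <- function(result, k = 10L) {
  if (k > length(result$ordered_features)) stop_ppght("k exceeds ranking length")
  utils::head(result$ordered_features, k)
}

feature_matrix <- function(table) as.matrix(table[feature_columns(table)])

as_binary <- function(labels) {
  f <- if (is.factor(labels)) labels else factor(labels)
  if (nlevels(f) != 2L) stop_ppght("need exactly 2 classes, got %d", nlevels(f))
  f
}

#' Correlation report of features against a continuous target
#'
#' Pearson correlation (with a two-sided p-value) of every feature against
#' the target, sorted by absolute correlation; the standard report pairs the
#' morphological features with systolic blood pressure. Constant features are
#' excluded with a message.
#'
#' @param table A feature table.
#' @param target Numeric vector (defaults to `table$sbp`) .
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame `feature, r, p` sorted by `|r|` descending.
#' @export
correlation_report <- function(table, target = table$sbp, method = "pearson") {
  fc <- feature_columns(table)
  rows <- lapply(fc, function(f) {
    x <- table[[f]]
    ok <- stats::complete.cases(x, target)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0) return(NULL)
    ct <- stats::cor.test(x[ok], target[ok], method = method, exact = FALSE)
    data.frame(feature = f, r = unname(ct$estimate), p = ct$p.value)
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0L) message(dropped, " constant/degenerate feature(s) excluded")
  out <- do.call(rbind, rows)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Spearman-correlation feature ranking
#'
#' Score = |Spearman rho| between the feature and the 0/1 class label.
#'
#' @param table Feature table.
#' @param labels Binary class labels.
#' @return A `ppg_ranking`.
#' @export
spearman_rank <- function(table, labels) {
  y <- as.integer(as_binary(labels)) - 1L
  X <- feature_matrix(table)
  s <- apply(X, 2L, function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0) return(0)
    abs(stats::cor(x[ok], y[ok], method = "spearman"))
  })
  ranking_result("spearman", s, colnames(X))
}

#' ReliefF feature weighting
#'
#' Standard ReliefF: every instance in turn contributes the mean
#' range-normalized difference to its `k` nearest hits (same class, weight
#' decrement) and `k` nearest misses (other class, increment weighted by the
#' class prior). Distances are Manhattan on the range-normalized features.
#' Deterministic because all instances are used in order rather than sampled.
#'
#' @param table Feature table.
#' @param labels Class labels (2+ classes supported).
#' @param k_neighbors Neighbours per class (default 10; truncated with a
#'   warning if a class is too small).
#' @return A `ppg_ranking` with weights in `[-1, 1]`.
#' @export
relieff <- function(table, labels, k_neighbors = 10L) {
  y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  X <- feature_matrix(table)
  # median-impute per feature so distances are defined
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- stats::median(X[, j], na.rm = TRUE)
  }
  rng <- apply(X, 2L, function(x) diff(range(x)))
  rng[rng == 0 | is.na(rng)] <- 1
  Xn <- sweep(X, 2L, rng, "/")
  n <- nrow(Xn)
  min_class <- min(table(y))
  k <- k_neighbors
  if (min_class <= k) {
    k <- max(1L, min_class - 1L)
    warning(sprintf("k_neighbors truncated to %d (smallest class has %d members)",
                    k, min_class), call. = FALSE)
  }
  prior <- table(y) / n
  W <- numeric(ncol(Xn))
  tXn <- t(Xn)
  for (i in seq_len(n)) {
    d <- colSums(abs(tXn - Xn[i, ]))  # Manhattan distances to all points
    d[i] <- Inf
    same <- y == y[i]
    hits <- order(d + ifelse(same, 0, Inf))[seq_len(k)]
    W <- W - colMeans(abs(Xn[hits, , drop = FALSE] -
                          rep(Xn[i, ], each = k))) / n
    for (cl in levels(y)[levels(y) != y[i]]) {
      inc <- y == cl
      misses <- order(d + ifelse(inc, 0, Inf))[seq_len(k)]
      wc <- prior[[cl]] / (1 - prior[[as.character(y[i])]])
      W <- W + wc * colMeans(abs(Xn[misses, , drop = FALSE] -
                                 rep(Xn[i, ], each = k))) / n
    }
  }
  ranking_result("relieff", W, colnames(X))
}

# Equal-frequency discretization into at most n_bins bins (1-based ids).
equal_freq_bins <- function(x, n_bins) {
  ok <- !is.na(x)
  br <- unique(stats::quantile(x[ok], probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE, type = 7))
  ids <- rep(NA_integer_, length(x))
  ids[ok] <- findInterval(x[ok], br, rightmost.closed = TRUE, all.inside = TRUE)
  ids
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# H(y) - H(y | bin) in bits, pairwise-complete.
mi_binned <- function(bin, y) {
  ok <- !is.na(bin)
  bin <- bin[ok]; y <- y[ok]
  tb <- table(bin, y)
  hy <- entropy_bits(table(y))
  hcond <- sum(rowSums(tb) / sum(tb) * apply(tb, 1L, entropy_bits))
  hy - hcond
}

#' Information-gain feature ranking
#'
#' Score = H(class) - H(class | binned feature) in bits, with equal-frequency
#' binning.
#'
#' @inheritParams spearman_rank
#' @param n_bins Number of bins (>= 2, default 10).
#' @return A `ppg_ranking`.
#' @export
info_gain <- function(table, labels, n_bins = 10L) {
  if (n_bins < 2L) stop_ppght("n_bins must be >= 2")
  y <- as_binary(labels)
  X <- feature_matrix(table)
  s <- apply(X, 2L, function(x) mi_binned(equal_freq_bins(x, n_bins), y))
  ranking_result("info_gain", s, colnames(X))
}

#' Chi-square feature ranking
#'
#' Score = chi-square statistic of the binned-feature-by-class contingency
#' table (empty bins dropped before the statistic).
#'
#' @inheritParams info_gain
#' @return A `ppg_ranking`.
#' @export
chi_square <- function(table, labels, n_bins = 10L) {
  if (n_bins < 2L) stop_ppght("n_bins must be >= 2")
  y <- as_binary(labels)
  X <- feature_matrix(table)
  s <- apply(X, 2L, function(x) {
    bin <- equal_freq_bins(x, n_bins)
    ok <- !is.na(bin)
    tb <- table(bin[ok], y[ok])
    tb <- tb[rowSums(tb) > 0, , drop = FALSE]
    if (nrow(tb) < 2L) return(0)
    E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    sum((tb - E)^2 / E)
  })
  ranking_result("chi2", s, colnames(X))
}

#' Greedy mRMR feature ranking
#'
#' Mutual-information difference scheme on equal-frequency-discretized
#' features: the first pick maximizes MI with the class; each later pick
#' maximizes MI(class) minus the mean MI with the already-picked features.
#' The greedy pick order is the ranking.
#'
#' @inheritParams info_gain
#' @param k Ranking length (default: all features).
#' @return A `ppg_ranking` whose scores are the greedy objective at each pick.
#' @export
mrmr <- function(table, labels, k = NULL, n_bins = 10L) {
  y <- as_binary(labels)
  X <- feature_matrix(table)
  p <- ncol(X)
  k <- min(k %||% p, p)
  bins <- apply(X, 2L, equal_freq_bins, n_bins = n_bins)
  rel <- apply(bins, 2L, mi_binned, y = y)
  picked <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p)  # running sum of MI(feature, picked)
  for (step in seq_len(k)) {
    obj <- rel - if (step == 1L) 0 else red_sum / (step - 1L)
    obj[picked] <- -Inf
    j <- which.max(obj)  # first max = catalogue-order tie break
    picked <- c(picked, j)
    scores <- c(scores, obj[j])
    if (step < k) {
      add <- vapply(seq_len(p), function(i) {
        if (i %in% picked) 0 else mi_binned(bins[, i], factor(bins[, j]))
      }, 0)
      red_sum <- red_sum + add
    }
  }
  ranking_result("mrmr", scores, colnames(X), ordered = colnames(X)[picked])
}

#' Gini-index feature ranking
#'
#' Score = Gini impurity of the class prior minus the bin-weighted mean Gini
#' impurity within equal-frequency feature bins (impurity reduction).
#'
#' @inheritParams info_gain
#' @return A `ppg_ranking`.
#' @export
gini_index <- function(table, labels, n_bins = 10L) {
  if (n_bins < 2L) stop_ppght("n_bins must be >= 2")
  y <- as_binary(labels)
  gini <- function(counts) {
    p <- counts / sum(counts)
    1 - sum(p^2)
  }
  X <- feature_matrix(table)
  s <- apply(X, 2L, function(x) {
    bin <- equal_freq_bins(x, n_bins)
    ok <- !is.na(bin)
    if (!any(ok)) return(0)
    tb <- table(bin[ok], y[ok])
    prior <- gini(colSums(tb))
    within <- sum(rowSums(tb) / sum(tb) * apply(tb, 1L, gini))
    prior - within
  })
  ranking_result("gini", s, colnames(X))
}

#' Rank features by any of the six methods
#'
#' @param table Feature table.
#' @param labels Binary class labels.
#' @param method One of `"spearman"`, `"relieff"`, `"info_gain"`, `"chi2"`,
#'   `"mrmr"`, `"gini"`.
#' @param n_bins Bins for the discretization-based methods.
#' @param k_neighbors ReliefF neighbourhood size.
#' @param k mRMR ranking length.
#' @return A `ppg_ranking`.
#' @export
rank_features <- function(table, labels, method, n_bins = 10L,
                          k_neighbors = 10L, k = NULL) {
  switch(method,
    spearman = spearman_rank(table, labels),
    relieff = relieff(table, labels, k_neighbors),
    info_gain = info_gain(table, labels, n_bins),
    chi2 = chi_square(table, labels, n_bins),
    mrmr = mrmr(table, labels, k, n_bins),
    gini = gini_index(table, labels, n_bins),
    stop_ppght("unknown selection method '%s'", method))
}
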