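# Six feature-ranking methods against naive oracles and invariances.

test_that("correlation report recovers affine relations and independence", {
  set.seed(2)
  sbp <- runif(1000, 90, 180)
  X <- cbind(affine = 2 * sbp + 5, noise = rnorm(1000), const = rep(1, 1000))
  tab <- as_feature_table(X, sbp = sbp)
  expect_message(rep <- correlation_report(tab), "constant")
  expect_equal(rep$r[rep$feature == "affine"], 1, tolerance = 1e-12)
  expect_lt(abs(rep$r[rep$feature == "noise"]), 0.1)
  expect_false("const" %in% rep$feature)
  expect_identical(rep$feature[1L], "affine")  # sorted by |r|
  # symmetry of r under swapping the roles
  x <- rnorm(50); y <- 3 * x + rnorm(50)
  expect_equal(cor(x, y), cor(y, x))
})

test_that("spearman ranking matches the rank-formula oracle", {
  n <- 40L
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  x_mono <- c(sort(rnorm(n / 2)), sort(rnorm(n / 2)) + 10)  # all pos above all neg
  set.seed(7)
  x_null <- rnorm(n)
  tab <- as_feature_table(cbind(mono = x_mono, null = x_null))
  r <- spearman_rank(tab, y)
  # oracle: Spearman rho of ranks against the 0/1 label, computed directly
  rho <- function(x) {
    rx <- rank(x); ry <- rank(as.integer(y))
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(unname(r$scores["mono"]), abs(rho(x_mono)), tolerance = 1e-12)
  expect_identical(r$ordered_features[1L], "mono")
  set.seed(8)
  big <- as_feature_table(cbind(f = rnorm(500)))
  yy <- factor(rep(c("neg", "pos"), 250), levels = c("neg", "pos"))
  expect_lt(spearman_rank(big, yy)$scores[["f"]], 0.15)
})

test_that("relieff matches a naive double-loop oracle on a small dataset", {
  set.seed(11)
  n <- 16L
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  X <- cbind(sep = ifelse(y == "pos", 1, 0) + rnorm(n, 0, 0.05),
             noise = rnorm(n))
  tab <- as_feature_table(X)
  r <- relieff(tab, y, k_neighbors = 3L)
  W <- oracle_relieff(X, y, k = 3L)
  expect_equal(unname(r$scores[colnames(X)]), W, tolerance = 1e-10)
  expect_identical(r$ordered_features[1L], "sep")
  expect_true(all(r$scores >= -1 & r$scores <= 1))
})

test_that("relieff permutation null drives the top weight toward zero", {
  set.seed(21)
  n <- 500L
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(sample(rep(c("neg", "pos"), n / 2)), levels = c("neg", "pos"))
  r <- relieff(as_feature_table(X), y, k_neighbors = 10L)
  expect_lt(max(r$scores), 0.05)
})

test_that("information gain matches entropy identities", {
  n <- 100L
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  perfect <- as.integer(y == "pos") + seq_len(n) * 1e-9  # continuous perfect predictor
  set.seed(3)
  indep <- rnorm(1000)
  y2 <- factor(rep(c("neg", "pos"), 500), levels = c("neg", "pos"))
  r1 <- info_gain(as_feature_table(cbind(perfect = perfect)), y, n_bins = 2L)
  expect_equal(unname(r1$scores["perfect"]), 1)  # H(balanced binary class) = 1 bit
  r2 <- info_gain(as_feature_table(cbind(f = indep)), y2)
  expect_lt(r2$scores[["f"]], 0.05)
  expect_true(all(r1$scores >= 0) && all(r2$scores >= 0))
  expect_error(info_gain(as_feature_table(cbind(f = indep)), y2, n_bins = 1L), "n_bins")
})

test_that("chi-square statistic matches the closed-form 2x2 value", {
  # contingency [[10, 0], [0, 10]] has chi2 = 20
  y <- factor(rep(c("neg", "pos"), each = 10), levels = c("neg", "pos"))
  x <- as.numeric(y == "pos")
  r <- chi_square(as_feature_table(cbind(f = x)), y, n_bins = 2L)
  expect_equal(unname(r$scores["f"]), 20)
  # independent uniform table ~ 0; statistic is never negative
  set.seed(5)
  r2 <- chi_square(as_feature_table(cbind(f = rnorm(2000))),
                   factor(rep(c("neg", "pos"), 1000), levels = c("neg", "pos")))
  expect_true(r2$scores[["f"]] >= 0)
})

test_that("mrmr penalizes duplicated features", {
  set.seed(13)
  n <- 60L
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  strong <- as.integer(y == "pos") + rnorm(n, 0, 0.1)
  weak <- as.integer(y == "pos") + rnorm(n, 0, 1.2)
  tab <- as_feature_table(cbind(strong = strong, dup = 2 * strong + 1, weak = weak))
  r <- mrmr(tab, y, k = 3L)
  expect_identical(r$ordered_features[1L], "strong")
  expect_identical(r$ordered_features[2L], "weak")  # duplicate deferred
  # oracle check of the first pick: max MI with the class
  bins <- apply(cbind(strong, 2 * strong + 1, weak), 2,
                function(v) cut(v, unique(quantile(v, 0:10 / 10)), include.lowest = TRUE))
  mis <- apply(bins, 2, oracle_mi, b = y)
  expect_identical(unname(which.max(mis)), 1L)
  # k = 1 reduces to max relevance; output length honors k
  expect_length(top_k(mrmr(tab, y, k = 1L), 1L), 1L)
  expect_length(mrmr(tab, y, k = 2L)$ordered_features, 2L)
})

test_that("gini reduction spans [0, prior impurity]", {
  n <- 100L
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  perfect <- as.integer(y == "pos") + seq_len(n) * 1e-9
  r <- gini_index(as_feature_table(cbind(perfect = perfect)), y, n_bins = 2L)
  expect_equal(unname(r$scores["perfect"]), 0.5)  # balanced prior impurity
  set.seed(9)
  r2 <- gini_index(as_feature_table(cbind(f = rnorm(1000))),
                   factor(rep(c("neg", "pos"), 500), levels = c("neg", "pos")))
  expect_lt(r2$scores[["f"]], 0.05)
  expect_gte(r2$scores[["f"]], -1e-12)
})

test_that("rankings are permutations, prefixes nest, ties follow input order", {
  pt <- planted_table(n = 60, p = 20, seed = 4)
  for (m in c("spearman", "relieff", "info_gain", "chi2", "gini")) {
    r <- rank_features(pt$table, pt$labels, m)
    expect_setequal(r$ordered_features, feature_columns(pt$table))
    expect_true(all(diff(r$scores) <= 1e-12))          # non-increasing
    expect_identical(top_k(r, 5L), top_k(r, 10L)[1:5]) # prefix property
  }
  r <- mrmr(pt$table, pt$labels)
  expect_setequal(r$ordered_features, feature_columns(pt$table))
  expect_error(top_k(r, 99L), "exceeds")
  expect_length(top_k(r, 0L), 0L)
})

test_that("scores are invariant to feature order and monotone transforms", {
  pt <- planted_table(n = 80, p = 8, seed = 6)
  tab <- pt$table; y <- pt$labels
  fc <- feature_columns(tab)
  tab_rev <- tab[c("subject_id", "sbp", "dbp", "bp_class", rev(fc))]
  for (m in c("spearman", "info_gain", "chi2", "gini", "relieff")) {
    r1 <- rank_features(tab, y, m)
    r2 <- rank_features(tab_rev, y, m)
    expect_equal(r1$scores[fc], r2$scores[fc], tolerance = 1e-12)
  }
  # strictly increasing transform leaves discretized scores unchanged
  tab_t <- tab
  tab_t[["planted"]] <- exp(tab_t[["planted"]])
  for (m in c("spearman", "info_gain", "chi2", "gini")) {
    r1 <- rank_features(tab, y, m)
    r2 <- rank_features(tab_t, y, m)
    expect_equal(r1$scores[["planted"]], r2$scores[["planted"]], tolerance = 1e-12)
  }
})
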