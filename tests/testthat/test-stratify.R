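# BP class assignment, classifiers, cross-validation and reporting.

test_that("assign_bp_class applies the criteria with hypertension precedence", {
  expect_identical(as.character(assign_bp_class(145, 85)), "hypertensive")
  expect_identical(as.character(assign_bp_class(118, 82)), "prehypertensive")
  expect_identical(as.character(assign_bp_class(119, 79)), "normotensive")
  expect_identical(as.character(assign_bp_class(125, 95)), "hypertensive")  # precedence
  expect_identical(as.character(assign_bp_class(140, 60)), "hypertensive")
  expect_identical(as.character(assign_bp_class(120, 60)), "prehypertensive")
  expect_error(assign_bp_class(30, 70), "SBP")
  expect_error(assign_bp_class(120, 210), "DBP")
})

test_that("pairing splits pool the right groups with pos = higher BP", {
  tab <- data.frame(subject_id = as.character(1:9), sbp = 0, dbp = 0,
                    bp_class = rep(c("normotensive", "prehypertensive", "hypertensive"), 3))
  sp <- pairing_split(tab, "normpre_vs_hyp")
  expect_identical(sum(sp$labels == "pos"), 3L)
  expect_identical(sum(sp$labels == "neg"), 6L)
  sp2 <- pairing_split(tab, "norm_vs_pre")
  expect_identical(nrow(sp2$table), 6L)
  expect_identical(levels(sp2$labels), c("neg", "pos"))
})

test_that("weighted KNN honors the exact-match convention", {
  X <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE)
  y <- factor(c("neg", "neg", "pos"), levels = c("neg", "pos"))
  pred <- fit_predict("weighted_knn", X, y, X[3, , drop = FALSE])
  expect_identical(as.character(pred), "pos")
})

test_that("all four classifiers solve a separable two-cluster toy exactly", {
  set.seed(31)
  n <- 40L
  X <- rbind(matrix(rnorm(n * 2, -3, 0.3), n, 2), matrix(rnorm(n * 2, 3, 0.3), n, 2))
  y <- factor(rep(c("neg", "pos"), each = n), levels = c("neg", "pos"))
  Xt <- rbind(matrix(rnorm(20, -3, 0.3), 10, 2), matrix(rnorm(20, 3, 0.3), 10, 2))
  yt <- factor(rep(c("neg", "pos"), each = 10), levels = c("neg", "pos"))
  for (cl in c("lda", "logistic", "cubic_svm", "weighted_knn")) {
    pred <- fit_predict(cl, X, y, Xt)
    expect_identical(as.character(pred), as.character(yt))
  }
  expect_error(fit_predict("lda", X, factor(rep("neg", 2 * n)), Xt), "2 classes")
})

test_that("label-permuted training yields chance-level accuracy", {
  set.seed(32)
  n <- 200L
  X <- matrix(rnorm(n * 5), n, 5)
  y <- factor(sample(rep(c("neg", "pos"), n / 2)), levels = c("neg", "pos"))
  Xt <- matrix(rnorm(400 * 5), 400, 5)
  yt <- factor(sample(rep(c("neg", "pos"), 200)), levels = c("neg", "pos"))
  for (cl in c("lda", "logistic", "weighted_knn")) {
    acc <- mean(fit_predict(cl, X, y, Xt) == yt)
    expect_gt(acc, 0.4); expect_lt(acc, 0.6)
  }
})

test_that("metrics identities: SE/PP/F1 from pooled confusion counts", {
  expect_equal(f1_score(100, 100), 100)
  expect_equal(f1_score(50, 0), 0)
  expect_true(is.na(f1_score(0, 0)))
  # harmonic-mean identity at an arbitrary point
  pp <- 73.2; se <- 61.8
  expect_equal(f1_score(pp, se), 2 * pp * se / (pp + se))
})

test_that("stratified folds keep every class in every fold", {
  y <- factor(rep(c("neg", "pos"), c(48, 35)), levels = c("neg", "pos"))
  ids <- ppght:::stratified_fold_ids(y, 10L, seed = 17L)
  expect_identical(sort(unique(ids)), 1:10)
  for (f in 1:10) {
    expect_true(all(table(y[ids == f]) >= 1))
    expect_true(all(table(y[ids != f]) >= 2))
  }
  expect_warning(ids2 <- ppght:::stratified_fold_ids(factor(rep(c("a", "b"), c(50, 4))), 10L),
                 "reduced")
  expect_lte(max(ids2), 4L)
})

test_that("cross-validation pools counts to the cohort size and is deterministic", {
  pt <- planted_table(n = 83, p = 15, shift = 2.5, seed = 14)
  tab <- pt$table
  tab$bp_class <- ifelse(pt$labels == "pos", "hypertensive", "normotensive")
  r1 <- stratified_10fold(tab, "norm_vs_hyp", "spearman", "lda", k = 5L, seed = 17L)
  expect_identical(r1$TP + r1$FN, sum(pt$labels == "pos"))
  expect_identical(r1$TN + r1$FP, sum(pt$labels == "neg"))
  expect_equal(r1$F1, f1_score(r1$PP, r1$SE), tolerance = 0.01)
  r2 <- stratified_10fold(tab, "norm_vs_hyp", "spearman", "lda", k = 5L, seed = 17L)
  expect_identical(r1, r2)
  # planted signal is learnable
  expect_gt(r1$F1, 80)
})

test_that("fold preprocessing depends only on training rows (no leakage)", {
  set.seed(41)
  Xtr <- matrix(rnorm(50 * 6), 50, 6)
  Xte1 <- matrix(rnorm(10 * 6), 10, 6)
  Xte2 <- matrix(rnorm(10 * 6, 5, 3), 10, 6)
  p1 <- ppght:::fold_prepare(Xtr, Xte1)
  p2 <- ppght:::fold_prepare(Xtr, Xte2)
  expect_identical(p1$train, p2$train)
  # selection sees only training rows: ranking is a pure function of them
  pt <- planted_table(n = 60, p = 10, seed = 15)
  r1 <- rank_features(pt$table[1:40, ], pt$labels[1:40], "spearman")
  r2 <- rank_features(pt$table[1:40, ], pt$labels[1:40], "spearman")
  expect_identical(r1$ordered_features, r2$ordered_features)
})

test_that("run_experiment covers the full grid and flags winners", {
  pt <- planted_table(n = 45, p = 8, shift = 2, seed = 16)
  tab <- pt$table
  tab$bp_class <- rep(c("normotensive", "prehypertensive", "hypertensive"), 15)
  rep <- suppressWarnings(
    run_experiment(tab, methods = c("spearman", "gini"),
                   classifiers = c("lda", "weighted_knn"), k = 4L, nfolds = 5L,
                   seed = 17L))
  expect_identical(nrow(rep), 3L * 2L * 2L)
  expect_identical(sum(rep$best), 3L)
  for (p in unique(rep$pairing)) {
    sub <- rep[rep$pairing == p, ]
    expect_equal(sub$F1[sub$best], max(sub$F1), tolerance = 1e-12)
    expect_true(all(sub$TP + sub$FN == sub$TP[1] + sub$FN[1]))
  }
  rep2 <- suppressWarnings(
    run_experiment(tab, methods = c("spearman", "gini"),
                   classifiers = c("lda", "weighted_knn"), k = 4L, nfolds = 5L,
                   seed = 17L))
  expect_identical(rep, rep2)
  expect_error(run_experiment(tab[tab$bp_class != "hypertensive", ]), "three")
})
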