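#' Binary classifiers for the stratification experiments
#'
#' Four fixed-configuration learners, all deterministic: linear discriminant
#' analysis (pooled covariance with a small ridge for rank safety), logistic
#' regression (IRLS maximum likelihood with a tiny L2 guard against
#' separation), a cubic-kernel soft-margin SVM (`K(u, v) = (1 + u.v / d)^3`,
#' box constraint C = 1, solved by a deterministic SMO), and
#' distance-weighted KNN with K = 10 and inverse-squared-distance votes
#' (an exact training match dominates the vote).
#'
#' @name classifiers
NULL

#' Fit on a training split and predict a test split
#'
#' @param classifier One of `"lda"`, `"logistic"`, `"cubic_svm"`,
#'   `"weighted_knn"`.
#' @param train_x,test_x Numeric matrices (rows = subjects).
#' @param train_y Factor with exactly two levels (negative first).
#' @return Factor of predicted labels for `test_x`, levels as `train_y`.
#' @export
fit_predict <- function(classifier, train_x, train_y, test_x) {
  train_y <- as_binary(train_y)
  if (min(table(train_y)) == 0L) stop_ppght("training fold lost a class")
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  pred <- switch(classifier,
    lda = predict_lda(train_x, train_y, test_x),
    logistic = predict_logistic(train_x, train_y, test_x),
    cubic_svm = predict_svm(train_x, train_y, test_x),
    weighted_knn = predict_wknn(train_x, train_y, test_x),
    stop_ppght("unknown classifier '%s'", classifier))
  factor(levels(train_y)[pred + 1L], levels = levels(train_y))
}

# ---- LDA -------------------------------------------------------------------

predict_lda <- function(X, y, Xt) {
  pos <- y == levels(y)[2L]
  mu0 <- colMeans(X[!pos, , drop = FALSE])
  mu1 <- colMeans(X[pos, , drop = FALSE])
  n <- nrow(X)
  S <- (crossprod(sweep(X[!pos, , drop = FALSE], 2L, mu0)) +
        crossprod(sweep(X[pos, , drop = FALSE], 2L, mu1))) / (n - 2L)
  S <- S + diag(1e-8 * max(mean(diag(S)), 1e-12), ncol(X))
  w <- solve(S, mu1 - mu0)
  # threshold from the midpoint shifted by the log prior ratio
  thr <- as.numeric(t(w) %*% (mu0 + mu1)) / 2 - log(mean(pos) / (1 - mean(pos)))
  as.integer(Xt %*% w > thr)
}

# ---- logistic regression ---------------------------------------------------

predict_logistic <- function(X, y, Xt, lambda = 1e-6, max_iter = 100L) {
  X1 <- cbind(1, X)
  yv <- as.numeric(y == levels(y)[2L])
  beta <- numeric(ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X))))  # intercept unpenalized
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X1 %*% beta), -30), 30)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X1 * w, X1) + pen
    g <- crossprod(X1, yv - p) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  as.integer(drop(cbind(1, Xt) %*% beta) > 0)
}

# ---- cubic SVM (deterministic SMO) -----------------------------------------

cubic_kernel <- function(A, B) (1 + tcrossprod(A, B) / ncol(A))^3

predict_svm <- function(X, y, Xt, C = 1, tol = 1e-3, max_passes = 20L) {
  yv <- ifelse(y == levels(y)[2L], 1, -1)
  n <- nrow(X)
  K <- cubic_kernel(X, X)
  alpha <- numeric(n)
  b <- 0
  err <- function(i) sum(alpha * yv * K[, i]) + b - yv[i]
  E <- vapply(seq_len(n), err, 0)
  passes <- 0L
  total <- 0L
  while (passes < max_passes && total < 500L) {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- E[i]
      if ((yv[i] * Ei < -tol && alpha[i] < C) || (yv[i] * Ei > tol && alpha[i] > 0)) {
        j <- which.max(abs(E - Ei) + ifelse(seq_len(n) == i, -Inf, 0))
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (yv[i] != yv[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - yv[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-5) next
        ai <- ai_old + yv[i] * yv[j] * (aj_old - aj)
        b1 <- b - Ei - yv[i] * (ai - ai_old) * K[i, i] - yv[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - yv[i] * (ai - ai_old) * K[i, j] - yv[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
        alpha[i] <- ai; alpha[j] <- aj
        E <- drop(K %*% (alpha * yv)) + b - yv
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    total <- total + 1L
  }
  f <- drop(cubic_kernel(Xt, X) %*% (alpha * yv)) + b
  as.integer(f > 0)
}

# ---- weighted KNN ----------------------------------------------------------

predict_wknn <- function(X, y, Xt, k = 10L) {
  yv <- as.integer(y == levels(y)[2L])
  k <- min(k, nrow(X))
  apply(Xt, 1L, function(q) {
    d2 <- colSums((t(X) - q)^2)
    if (any(d2 < 1e-20)) return(as.integer(mean(yv[d2 < 1e-20]) >= 0.5))
    nn <- order(d2)[seq_len(k)]
    w <- 1 / d2[nn]
    as.integer(sum(w * yv[nn]) / sum(w) > 0.5)
  })
}
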