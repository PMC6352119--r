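# Independent oracles: closed-form calculus on the generator's beat model,
# and naive reference implementations of the statistics under test. These
# deliberately share no code with the package internals.

# Fixed, deterministic pulse parameters (no RNG) for fixture beats.
make_params <- function(t_sys = 0.18, delay = 0.16, dic_gap = 0.13,
                        amp_refl = 0.55, amp_dic = 0.14,
                        w_sys = 0.047, w_refl = 0.062, w_dic = 0.057,
                        runoff = 0.25) {
  list(t_sys = t_sys, t_refl = t_sys + delay, t_dicrotic = t_sys + delay + dic_gap,
       amp_sys = 1, amp_refl = amp_refl, amp_dicrotic = amp_dic,
       width_sys = w_sys, width_refl = w_refl, width_dicrotic = w_dic,
       runoff_amp = runoff, noise_sd = 0, baseline_drift_amp = 0,
       drift_freq = 0.25)
}

# Closed-form beat model and its first two derivatives.
beat_value <- function(t, p, period) {
  g <- function(a, mu, s) a * exp(-0.5 * ((t - mu) / s)^2)
  g(p$amp_sys, p$t_sys, p$width_sys) +
    g(p$amp_refl, p$t_refl, p$width_refl) +
    g(p$amp_dicrotic, p$t_dicrotic, p$width_dicrotic) +
    (p$runoff_amp %||0% 0) * 0.5 * (1 - cos(2 * pi * t / period))
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

beat_d1 <- function(t, p, period) {
  g1 <- function(a, mu, s) -a * (t - mu) / s^2 * exp(-0.5 * ((t - mu) / s)^2)
  g1(p$amp_sys, p$t_sys, p$width_sys) +
    g1(p$amp_refl, p$t_refl, p$width_refl) +
    g1(p$amp_dicrotic, p$t_dicrotic, p$width_dicrotic) +
    (p$runoff_amp %||0% 0) * 0.5 * (2 * pi / period) * sin(2 * pi * t / period)
}

beat_d2 <- function(t, p, period) {
  g2 <- function(a, mu, s) a * ((t - mu)^2 / s^4 - 1 / s^2) * exp(-0.5 * ((t - mu) / s)^2)
  g2(p$amp_sys, p$t_sys, p$width_sys) +
    g2(p$amp_refl, p$t_refl, p$width_refl) +
    g2(p$amp_dicrotic, p$t_dicrotic, p$width_dicrotic) +
    (p$runoff_amp %||0% 0) * 0.5 * (2 * pi / period)^2 * cos(2 * pi * t / period)
}

# Analytic landmark times on a dense grid (independent of the detectors):
# S = argmax of the beat, w = argmax of d1, b = argmin of d2 near the
# systolic center, c = next local max of d2 after b.
oracle_landmarks <- function(p, period) {
  t <- seq(0, period, by = 1e-4)
  v <- beat_value(t, p, period)
  d1 <- beat_d1(t, p, period)
  d2 <- beat_d2(t, p, period)
  t_S <- t[which.max(v)]
  t_w <- t[which.max(d1)]
  t_b <- t[which.min(d2)]
  after_b <- t > t_b
  lmax <- which(diff(sign(diff(d2))) == -2) + 1L
  cands <- t[lmax][t[lmax] > t_b]
  t_c <- if (length(cands)) cands[1L] else NA_real_
  list(S = t_S, w = t_w, b = t_b, c = t_c)
}

# Closed-form integral of the beat model on [t1, t2] (for the area oracle).
beat_integral <- function(t1, t2, p, period) {
  gi <- function(a, mu, s) a * s * sqrt(2 * pi) * (pnorm((t2 - mu) / s) - pnorm((t1 - mu) / s))
  run <- (p$runoff_amp %||0% 0) * 0.5 *
    ((t2 - t1) - period / (2 * pi) * (sin(2 * pi * t2 / period) - sin(2 * pi * t1 / period)))
  gi(p$amp_sys, p$t_sys, p$width_sys) +
    gi(p$amp_refl, p$t_refl, p$width_refl) +
    gi(p$amp_dicrotic, p$t_dicrotic, p$width_dicrotic) + run
}

# Build a clean multi-beat waveform set (no filter: closed forms apply).
clean_wave <- function(p = make_params(), period = 0.8, fs = 1000, n_beats = 3) {
  beat <- synthesize_beat(p, period, fs)
  waveform_set(rep(beat, n_beats), fs, filter = FALSE)
}

# Naive direct-moment skewness.
oracle_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

# Naive ReliefF (binary, all instances, explicit loops; Manhattan distance on
# range-normalized features, class-prior-weighted misses).
oracle_relieff <- function(X, y, k) {
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  Xn <- sweep(X, 2, rng, "/")
  n <- nrow(Xn)
  W <- numeric(ncol(Xn))
  pr <- table(y) / n
  for (i in 1:n) {
    d <- sapply(1:n, function(j) sum(abs(Xn[i, ] - Xn[j, ])))
    d[i] <- Inf
    hits <- intersect(order(d), which(y == y[i]))[1:k]
    miss_cl <- setdiff(levels(y), as.character(y[i]))
    for (f in seq_len(ncol(Xn))) {
      W[f] <- W[f] - mean(abs(Xn[i, f] - Xn[hits, f])) / n
      for (cl in miss_cl) {
        misses <- intersect(order(d), which(y == cl))[1:k]
        wc <- pr[[cl]] / (1 - pr[[as.character(y[i])]])
        W[f] <- W[f] + wc * mean(abs(Xn[i, f] - Xn[misses, f])) / n
      }
    }
  }
  W
}

# Direct mutual information of two discrete vectors, in bits.
oracle_mi <- function(a, b) {
  tb <- table(a, b)
  p <- tb / sum(tb)
  pa <- rowSums(p); pb <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (pa[i] * pb[j]))
  s
}

# A feature table wrapper around a plain matrix (for selection tests).
as_feature_table <- function(X, sbp = NULL, bp_class = NULL) {
  df <- data.frame(subject_id = sprintf("T%03d", seq_len(nrow(X))),
                   sbp = sbp %||0% rep(120, nrow(X)),
                   dbp = rep(75, nrow(X)),
                   bp_class = bp_class %||0% rep("normotensive", nrow(X)),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(X))
}

# Synthetic planted-feature table: p-1 noise features plus one feature whose
# class means differ by `shift` within-class SDs.
planted_table <- function(n = 124, p = 125, shift = 3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("neg", "pos"), length.out = n), levels = c("neg", "pos"))
  X <- matrix(rnorm(n * p), n, p)
  X[, 1L] <- rnorm(n, mean = ifelse(y == "pos", shift, 0))
  colnames(X) <- c("planted", sprintf("noise_%03d", seq_len(p - 1L)))
  list(table = as_feature_table(X), labels = y)
}
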