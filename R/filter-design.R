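#' Chebyshev type-II bandpass filter design
#'
#' Designs a digital Chebyshev type-II (inverse Chebyshev) bandpass filter by
#' the classical analog-prototype route: analog lowpass prototype with unit
#' stopband edge, lowpass-to-bandpass transformation, and bilinear transform
#' with frequency prewarping. The design is returned as cascaded second-order
#' sections (one row per biquad, columns b0 b1 b2 a0 a1 a2); a high-order
#' bandpass with a sub-hertz edge is numerically unusable as a single
#' polynomial transfer function, so all filtering in this package runs on the
#' section cascade. The design order refers to the lowpass prototype; the
#' bandpass filter has twice that order.
#'
#' @param order Prototype order (bandpass order is `2 * order`).
#' @param low,high Stopband edge frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @param rs Stopband attenuation in dB (default 20).
#' @return List with `sos` (matrix of second-order sections) and `b`, `a`
#'   (single-polynomial coefficients, for inspection only).
#' @export
cheby2_bandpass <- function(order = 4, low = 0.5, high = 10, fs = 1000, rs = 20) {
  if (!is.numeric(fs) || fs <= 0) stop_ppght("fs must be positive")
  if (low <= 0 || high <= low) stop_ppght("need 0 < low < high")
  if (high >= fs / 2) stop_ppght("high edge %.3g Hz not below Nyquist (fs = %.3g Hz)", high, fs)
  if (order < 1) stop_ppght("order must be >= 1")

  zpk <- cheby2_proto(order, rs)
  # prewarp edges onto the analog axis used by the bilinear transform
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  zpk <- lp_to_bp(zpk, w0 = sqrt(w1 * w2), bw = w2 - w1)
  zpk <- bilinear_zpk(zpk, fs2)
  tf <- zpk_to_tf(zpk)
  list(sos = zpk_to_sos(zpk), b = tf$b, a = tf$a)
}

# Analog Chebyshev II lowpass prototype (stopband edge at 1 rad/s), zpk form.
cheby2_proto <- function(n, rs) {
  eps <- 1 / sqrt(10^(rs / 10) - 1)
  mu <- asinh(1 / eps) / n
  k <- seq_len(n)
  theta <- pi * (2 * k - 1) / (2 * n)
  # Chebyshev I poles for ripple eps, then invert for type II
  p1 <- complex(real = -sinh(mu) * sin(theta), imaginary = cosh(mu) * cos(theta))
  p <- 1 / p1
  ct <- cos(theta)
  z <- complex(imaginary = 1 / ct[abs(ct) > 1e-12])  # odd n drops the middle zero
  # unity gain at DC
  g <- Re(prod(-p)) / Re(prod(-z))
  list(z = z, p = p, k = g)
}

# Lowpass (edge 1 rad/s) -> bandpass (center w0, width bw), zpk form.
lp_to_bp <- function(zpk, w0, bw) {
  map <- function(x) {
    s <- x * bw / 2
    d <- sqrt(s^2 - w0^2 + 0i)
    c(s + d, s - d)
  }
  z <- unlist(lapply(zpk$z, map))
  p <- unlist(lapply(zpk$p, map))
  degree <- length(zpk$p) - length(zpk$z)
  z <- c(z, rep(0 + 0i, degree))  # zeros at infinity land at the origin
  list(z = z, p = p, k = zpk$k * bw^degree)
}

# Bilinear transform of an analog zpk system; fs2 = 2 * fs.
bilinear_zpk <- function(zpk, fs2) {
  zd <- (fs2 + zpk$z) / (fs2 - zpk$z)
  pd <- (fs2 + zpk$p) / (fs2 - zpk$p)
  kd <- zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p))
  degree <- length(zpk$p) - length(zpk$z)
  zd <- c(zd, rep(-1 + 0i, degree))  # analog zeros at infinity map to z = -1
  list(z = zd, p = pd, k = kd)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0i) - c(0i, p * ri)
  p
}

zpk_to_tf <- function(zpk) {
  b <- Re(zpk$k * poly_from_roots(zpk$z))
  a <- Re(poly_from_roots(zpk$p))
  list(b = b, a = a)
}

# Group complex roots into conjugate pairs (and real roots into pairs).
# Returns a list of length-2 complex vectors; a lone real root is paired
# with 0 (i.e. a first-order factor).
conj_pairs <- function(r, tol = 1e-10) {
  cplx <- r[Im(r) > tol]
  real <- sort(Re(r[abs(Im(r)) <= tol]))
  pairs <- lapply(cplx, function(x) c(x, Conj(x)))
  while (length(real) >= 2L) {
    pairs <- c(pairs, list(complex(real = real[1:2])))
    real <- real[-(1:2)]
  }
  if (length(real) == 1L) pairs <- c(pairs, list(complex(real = c(real, 0))))
  pairs
}

# Pair poles and zeros into second-order sections. Poles closest to the unit
# circle are matched first with their nearest zero pair; sections are ordered
# with those poles last, which keeps intermediate signals bounded.
zpk_to_sos <- function(zpk) {
  pp <- conj_pairs(zpk$p)
  zp <- conj_pairs(zpk$z)
  n_sec <- max(length(pp), length(zp))
  while (length(zp) < n_sec) zp <- c(zp, list(complex(real = c(0, 0))))
  while (length(pp) < n_sec) pp <- c(pp, list(complex(real = c(0, 0))))

  p_close <- order(vapply(pp, function(p) max(abs(abs(p) - 1)), 0))  # nearest unit circle first
  used <- logical(n_sec)
  assign <- integer(n_sec)
  for (i in p_close) {
    d <- vapply(seq_len(n_sec), function(j) {
      if (used[j]) Inf else Mod(pp[[i]][1L] - zp[[j]][1L])
    }, 0)
    j <- which.min(d)
    used[j] <- TRUE
    assign[i] <- j
  }
  biquad <- function(pair) {
    cf <- Re(poly_from_roots(pair))
    c(cf, rep(0, 3L - length(cf)))
  }
  sos <- t(vapply(seq_len(n_sec), function(i) {
    c(biquad(zp[[assign[i]]]), biquad(pp[[i]]))
  }, numeric(6)))
  # order sections so the pole pair nearest the unit circle comes last
  sos <- sos[rev(p_close), , drop = FALSE]
  sos[1L, 1:3] <- sos[1L, 1:3] * zpk$k
  sos
}

# Direct-form II transposed IIR filter with initial state zi (length max(nb,na)-1).
iir_filter <- function(b, a, x, zi = NULL) {
  b <- b / a[1L]; a <- a / a[1L]
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  z <- if (is.null(zi)) rep(0, nfilt - 1L) else zi
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (nfilt > 2L) {
      z[seq_len(nfilt - 2L)] <- b[2:(nfilt - 1L)] * xi + z[2:(nfilt - 1L)] - a[2:(nfilt - 1L)] * yi
    }
    z[nfilt - 1L] <- b[nfilt] * xi - a[nfilt] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial conditions for a unit-step input.
filter_zi <- function(b, a) {
  b <- b / a[1L]; a <- a / a[1L]
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  n <- nfilt - 1L
  # steady state of the transposed companion form: zi = (I - A)^{-1} B;
  # tol = 0 because a pole near z = 1 makes the system look singular to
  # R's rcond guard even though the solution is usable
  A <- matrix(0, n, n)
  A[, 1L] <- -a[2:nfilt]
  if (n > 1L) A[cbind(1:(n - 1L), 2:n)] <- 1
  B <- b[2:nfilt] - a[2:nfilt] * b[1L]
  solve(diag(n) - A, B, tol = 0)
}

# Per-section steady-state initial conditions, scaled by the cumulative DC
# gain of the preceding sections.
sosfilt_zi <- function(sos) {
  scale <- 1
  zi <- matrix(0, nrow(sos), 2L)
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    zi[s, ] <- scale * filter_zi(b, a)
    scale <- scale * sum(b) / sum(a)
  }
  zi
}

sosfilt <- function(sos, x, zi = NULL) {
  for (s in seq_len(nrow(sos))) {
    zs <- if (is.null(zi)) NULL else zi[s, ]
    x <- iir_filter(sos[s, 1:3], sos[s, 4:6], x, zs)
  }
  x
}

#' Zero-phase (forward-backward) filtering of second-order sections
#'
#' Applies a second-order-section cascade forwards and backwards so that the
#' net phase response is zero and landmark timing is preserved. Edge
#' transients are controlled by odd-reflection padding and steady-state
#' initial conditions, following the standard filtfilt construction.
#'
#' @param sos Second-order-section matrix (rows of b0 b1 b2 a0 a1 a2).
#' @param x Input samples.
#' @return Filtered samples, same length as `x`.
#' @export
sosfiltfilt <- function(sos, x) {
  padlen <- 3L * 2L * nrow(sos)
  n <- length(x)
  if (n <= padlen) stop_ppght("input too short (%d samples) for padlen %d", n, padlen)
  # odd reflection about the end points
  pre <- 2 * x[1L] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  ext <- c(pre, x, post)
  zi <- sosfilt_zi(sos)
  y <- sosfilt(sos, ext, zi * ext[1L])
  y <- rev(sosfilt(sos, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}
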