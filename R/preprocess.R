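#' Skewness signal-quality index
#'
#' Moment-based sample skewness `m3 / m2^(3/2)` of a PPG segment, used as a
#' signal-quality index: clean systolic-dominant pulse waves are right-tailed
#' and score high, while noisy or drift-dominated segments score near or
#' below zero. No small-sample bias correction is applied.
#'
#' @param samples Numeric vector, length >= 3.
#' @return Skewness value, or `NA_real_` (with a warning) for a constant
#'   segment, where the index is undefined.
#' @export
skewness_sqi <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 3L) stop_ppght("need at least 3 samples, got %d", length(samples))
  m <- mean(samples)
  m2 <- mean((samples - m)^2)
  if (m2 == 0) {
    warning("constant segment: skewness undefined", call. = FALSE)
    return(NA_real_)
  }
  mean((samples - m)^3) / m2^1.5
}

#' Select the best of a subject's records by skewness SQI
#'
#' Scores each record with [skewness_sqi()] and returns the argmax. Ties are
#' broken in favour of the earliest record.
#'
#' @param records List of records (each a list with a `samples` field) or a
#'   list of plain numeric vectors.
#' @return List with `skewness` (per-record scores), `selected` (1-based index
#'   into `records`) and `record_index` (the record's own 0-based index if it
#'   carries one).
#' @export
select_best_record <- function(records) {
  if (length(records) == 0L) stop_ppght("no records supplied")
  sk <- vapply(records, function(r) {
    x <- if (is.list(r)) r$samples else r
    skewness_sqi(x)
  }, 0)
  sel <- which(sk == max(sk, na.rm = TRUE))[1L]
  ri <- records[[sel]]$record_index %||% (sel - 1L)
  list(skewness = sk, selected = sel, record_index = ri)
}

#' Bandpass filter a PPG record
#'
#' Zero-phase fourth-order Chebyshev type-II bandpass (stopband edges 0.5 and
#' 10 Hz by default), removing baseline drift and high-frequency noise while
#' leaving pulse morphology and landmark timing undistorted.
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz (> 20).
#' @param low,high Stopband edges in Hz.
#' @param order Prototype design order.
#' @param rs Stopband attenuation in dB.
#' @return Filtered vector, same length as the input.
#' @export
bandpass_filter <- function(samples, fs, low = 0.5, high = 10, order = 4, rs = 20) {
  if (fs <= 20) stop_ppght("fs = %.3g Hz too low for a %.3g Hz band edge", fs, high)
  d <- cheby2_bandpass(order, low, high, fs, rs)
  sosfiltfilt(d$sos, as.numeric(samples))
}

#' Numerical derivative by central differences
#'
#' Central-difference derivative applied `order` times, scaled by `fs` per
#' application; endpoints use one-sided differences so the output keeps the
#' input length. Optionally each application is followed by a zero-phase
#' moving average (window ~20 ms): differentiation amplifies the
#' high-frequency noise that survives the bandpass stopband by (2 pi f)^2 per
#' order, which would otherwise bury the small APG waves of quantized
#' records. Smoothing is off by default so the bare operator matches its
#' closed-form calculus contract.
#'
#' @param samples Numeric vector, length >= 5.
#' @param fs Sampling rate in Hz.
#' @param order Number of derivative applications (1, 2 or 3).
#' @param smooth Apply the moving average after each application.
#' @param smooth_window Window length in samples (odd; default ~20 ms).
#' @return Numeric vector, same length as `samples`.
#' @export
differentiate <- function(samples, fs, order = 1, smooth = FALSE,
                          smooth_window = NULL) {
  x <- as.numeric(samples)
  if (length(x) < 5L) stop_ppght("need at least 5 samples")
  if (!order %in% 1:3) stop_ppght("order must be 1, 2 or 3")
  w <- smooth_window %||% max(5L, 2L * floor(0.01 * fs) + 1L)
  for (i in seq_len(order)) {
    x <- diff_once(x, fs)
    if (smooth) x <- moving_average(x, w)
  }
  x
}

# Zero-phase moving average; edges handled by replication padding.
moving_average <- function(x, w) {
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))[(half + 1L):(half + n)]
}

diff_once <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  d * fs
}

#' Build the four-level waveform set of a record
#'
#' Filters the raw PPG and computes its first (VPG), second (APG) and third
#' derivative on the same time base. Level indices used throughout the
#' package: 0 = PPG, 1 = VPG, 2 = APG, 3 = third derivative.
#'
#' @param samples Raw record samples.
#' @param fs Sampling rate in Hz.
#' @param filter Logical; apply the bandpass first (default TRUE).
#' @param smooth Smooth each derivative with the ~20 ms zero-phase moving
#'   average (default TRUE; see [differentiate()]).
#' @param ... Passed to [bandpass_filter()].
#' @return Object of class `waveform_set`: list with `ppg`, `vpg`, `apg`,
#'   `jerk` and `fs`.
#' @export
waveform_set <- function(samples, fs, filter = TRUE, smooth = TRUE, ...) {
  ppg <- if (filter) bandpass_filter(samples, fs, ...) else as.numeric(samples)
  vpg <- differentiate(ppg, fs, 1, smooth = smooth)
  apg <- differentiate(vpg, fs, 1, smooth = smooth)
  jerk <- differentiate(apg, fs, 1, smooth = smooth)
  structure(list(ppg = ppg, vpg = vpg, apg = apg, jerk = jerk, fs = fs),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("<waveform_set: %d samples @ %g Hz (ppg/vpg/apg/jerk)>\n",
              length(x$ppg), x$fs))
  invisible(x)
}

wave_level <- function(wave, level) {
  switch(level + 1L, wave$ppg, wave$vpg, wave$apg, wave$jerk,
         stop_ppght("waveform level %d out of range 0..3", level))
}
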