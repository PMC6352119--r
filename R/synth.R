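#' Synthetic PPG cohorts
#'
#' The generator emulates the layout and statistical structure of a short
#' fingertip-PPG screening study: three 2.1 s records per subject at 1 kHz
#' with 12-bit quantization, a subject metadata table with brachial SBP/DBP,
#' and cohort sizes 48/41/35 for the normotensive, prehypertensive and
#' hypertensive groups. Each beat is modelled as the sum of three positive
#' Gaussian bumps: the systolic (propulsion) wave, the reflected wave and the
#' dicrotic wave. Rising blood pressure is expressed as earlier and larger
#' wave reflection: the reflected-wave delay `t_refl - t_sys` decreases and
#' the amplitude ratio `amp_refl / amp_sys` increases monotonically from the
#' normotensive to the hypertensive class.
#'
#' @name synth
NULL

#' Draw a synthetic subject profile for a blood-pressure class
#'
#' SBP/DBP are drawn uniformly (integer mmHg) inside the class criteria;
#' pulse-shape parameters come from class-conditioned distributions whose
#' reflected-wave timing and amplitude shift monotonically with class
#' severity. `effect = 0` removes the class effect entirely (all classes
#' share the pooled pulse-shape distribution), which is the null world used
#' for calibration checks.
#'
#' @param bp_class One of `"normotensive"`, `"prehypertensive"`,
#'   `"hypertensive"`.
#' @param subject_id Identifier string.
#' @param effect Class effect scale in \[0, 1\]; 1 = full stated effect.
#' @return Object of class `subject_profile`.
#' @export
sample_subject <- function(bp_class, subject_id = "S000", effect = 1) {
  if (!bp_class %in% BP_CLASSES)
    stop_ppght("unknown bp_class '%s' (expected one of %s)",
               bp_class, paste(BP_CLASSES, collapse = ", "))
  bp <- switch(bp_class,
    normotensive = c(sample(90:119, 1L), sample(60:79, 1L)),
    prehypertensive = if (runif(1) < 0.5) {
      c(sample(120:139, 1L), sample(60:89, 1L))
    } else {
      c(sample(100:139, 1L), sample(80:89, 1L))
    },
    hypertensive = if (runif(1) < 0.5) {
      c(sample(140:180, 1L), sample(60:110, 1L))
    } else {
      c(sample(110:139, 1L), sample(90:110, 1L))
    })
  # class-graded reflection: delay shrinks, relative amplitude grows. The
  # within-class jitter is deliberately comparable to the between-class step
  # (adjacent classes overlap substantially, extreme classes much less), the
  # overlap structure real BP cohorts show.
  off <- switch(bp_class, normotensive = -1, prehypertensive = 0, hypertensive = 1)
  delay <- 0.15 - effect * off * 0.04 + runif(1, -0.04, 0.04)
  ampr <- 0.57 + effect * off * 0.15 + runif(1, -0.12, 0.12)
  # systolic center far enough into the beat that the Gaussian tail (and its
  # slope) is negligible at the wrap point, keeping the tiled record C1-smooth
  t_sys <- runif(1, 0.17, 0.21)
  pulse <- list(
    t_sys = t_sys,
    t_refl = t_sys + delay,
    t_dicrotic = t_sys + delay + runif(1, 0.11, 0.15),
    amp_sys = 1,
    amp_refl = ampr,
    amp_dicrotic = runif(1, 0.10, 0.18),
    width_sys = runif(1, 0.042, 0.052),
    width_refl = runif(1, 0.055, 0.070),
    width_dicrotic = runif(1, 0.050, 0.065),
    runoff_amp = runif(1, 0.20, 0.30),
    noise_sd = 0.02,
    baseline_drift_amp = 0.04,
    drift_freq = runif(1, 0.15, 0.35)
  )
  hr <- min(max(rnorm(1, 75, 8), 55), 100)
  structure(list(subject_id = subject_id, bp_class = bp_class,
                 sbp = bp[1L], dbp = bp[2L], heart_rate = hr,
                 pulse_params = pulse),
            class = "subject_profile")
}

#' Synthesize one noiseless PPG beat
#'
#' Deterministic sum of three positive Gaussian bumps (systolic, reflected,
#' dicrotic) plus a smooth diastolic-runoff term
#' `runoff_amp * (1 - cos(2 pi t / period)) / 2`, which vanishes exactly at
#' the beat boundaries so the pulse foot is the unambiguous beat minimum (a
#' bare Gaussian mixture would leave a flat inter-beat tail no onset detector
#' can anchor on). Noise and drift are added at the record level, not here.
#'
#' @param params Pulse-shape parameter list (see [sample_subject()]).
#' @param period Beat period in seconds (> `t_dicrotic`).
#' @param fs Sampling rate in Hz (>= 100).
#' @return Numeric vector of `round(period * fs)` samples.
#' @export
synthesize_beat <- function(params, period, fs) {
  if (period <= 0 || fs <= 0) stop_ppght("period and fs must be positive")
  if (fs < 100) stop_ppght("fs = %.3g Hz too low (need >= 100 Hz)", fs)
  if (period <= params$t_dicrotic)
    stop_ppght("period %.3g s must exceed t_dicrotic %.3g s", period, params$t_dicrotic)
  t <- (seq_len(round(period * fs)) - 1L) / fs
  gauss <- function(a, mu, s) a * exp(-0.5 * ((t - mu) / s)^2)
  runoff <- params$runoff_amp %||% 0
  gauss(params$amp_sys, params$t_sys, params$width_sys) +
    gauss(params$amp_refl, params$t_refl, params$width_refl) +
    gauss(params$amp_dicrotic, params$t_dicrotic, params$width_dicrotic) +
    runoff * 0.5 * (1 - cos(2 * pi * t / period))
}

#' Synthesize one raw record for a subject
#'
#' Tiles the subject's beat at their heart rate over the record duration,
#' adds Gaussian noise and a slow sinusoidal baseline drift, then quantizes
#' onto the 12-bit integer grid of the emulated acquisition front end.
#'
#' @param profile A `subject_profile`.
#' @param record_index 0-based record number within the subject.
#' @param duration Record length in seconds (default 2.1).
#' @param fs Sampling rate in Hz (default 1000).
#' @param noise_scale Multiplier on the profile's `noise_sd` (used to make
#'   the subject's records differ in quality).
#' @return List of class `raw_record` with `subject_id`, `record_index`,
#'   `samples` (integer ADC counts), `fs`.
#' @export
synthesize_record <- function(profile, record_index = 0L, duration = 2.1,
                              fs = 1000, noise_scale = 1) {
  period <- 60 / profile$heart_rate
  if (duration <= period) stop_ppght("duration must exceed one beat period")
  beat <- synthesize_beat(profile$pulse_params, period, fs)
  n <- round(duration * fs)
  x <- rep_len(beat, n)
  p <- profile$pulse_params
  if (p$noise_sd * noise_scale > 0) x <- x + rnorm(n, 0, p$noise_sd * noise_scale)
  if (p$baseline_drift_amp > 0) {
    t <- (seq_len(n) - 1L) / fs
    x <- x + p$baseline_drift_amp * sin(2 * pi * p$drift_freq * t + runif(1, 0, 2 * pi))
  }
  structure(list(subject_id = profile$subject_id,
                 record_index = as.integer(record_index),
                 samples = quantize_12bit(x), fs = fs),
            class = "raw_record")
}

# Map a.u. in [-0.5, 2.0] onto the 12-bit ADC grid (counts 0..4095).
quantize_12bit <- function(x, lo = -0.5, hi = 2.0) {
  counts <- round((x - lo) / (hi - lo) * 4095)
  as.integer(pmin(pmax(counts, 0), 4095))
}

#' Generate a synthetic cohort
#'
#' Draws `n_norm + n_pre + n_hyp` subjects with three records each, plus a
#' metadata table (`subject_id, age, sex, height_cm, weight_kg, sbp, dbp,
#' bp_class`). Anthropometrics are drawn around the cohort statistics of the
#' emulated screening study (age 55 +/- 16, height 163 +/- 8 cm, weight
#' 62 +/- 15 kg). Fully reproducible given `seed`.
#'
#' @param n_norm,n_pre,n_hyp Per-class subject counts.
#' @param seed Integer seed (optional; uses the current RNG state if NULL).
#' @param duration,fs Record geometry.
#' @param effect Class effect scale (see [sample_subject()]).
#' @return List with `records` (list of `raw_record`, 3 per subject) and
#'   `meta` (data.frame).
#' @export
generate_cohort <- function(n_norm, n_pre, n_hyp, seed = NULL,
                            duration = 2.1, fs = 1000, effect = 1) {
  if (any(c(n_norm, n_pre, n_hyp) < 0)) stop_ppght("counts must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  classes <- rep(BP_CLASSES, c(n_norm, n_pre, n_hyp))
  n <- length(classes)
  if (n == 0L) {
    empty <- data.frame(subject_id = character(0), age = integer(0),
                        sex = character(0), height_cm = integer(0),
                        weight_kg = integer(0), sbp = integer(0),
                        dbp = integer(0), bp_class = character(0),
                        stringsAsFactors = FALSE)
    return(list(records = list(), meta = empty))
  }
  records <- vector("list", 3L * n)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("S%03d", i)
    prof <- sample_subject(classes[i], id, effect = effect)
    noise_scales <- runif(3L, 0.5, 3)
    for (k in 0:2) {
      records[[3L * (i - 1L) + k + 1L]] <-
        synthesize_record(prof, k, duration, fs, noise_scale = noise_scales[k + 1L])
    }
    meta[[i]] <- data.frame(
      subject_id = id,
      age = min(max(round(rnorm(1, 55, 16)), 20), 90),
      sex = sample(c("M", "F"), 1L),
      height_cm = round(rnorm(1, 163, 8)),
      weight_kg = min(max(round(rnorm(1, 62, 15)), 35), 120),
      sbp = prof$sbp, dbp = prof$dbp,
      bp_class = classes[i],
      stringsAsFactors = FALSE
    )
  }
  list(records = records, meta = do.call(rbind, meta))
}
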