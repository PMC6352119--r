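#' Fiducial point delineation
#'
#' Landmarks are located per beat with a self-contained extrema search on the
#' PPG and its derivatives: O (onset), S (systolic peak), N (dicrotic notch)
#' and D (diastolic peak) on the PPG; w, x, y, z on the VPG; a, b, c, d, e on
#' the APG. All landmark times are 1-based sample indices into the record;
#' a landmark the waveform does not express is reported as `NA` (missingness
#' is data, never a silent zero). Native levels: O/S/N/D = 0 (PPG),
#' w/x/y/z = 1 (VPG), a..e = 2 (APG).
#'
#' @name fiducials
NULL

#' Segment a record into complete beats
#'
#' Beat boundaries are successive PPG local minima, each of which must
#' precede a VPG maximum (the steep systolic upslope) exceeding half the
#' record's median upslope-peak height. Partial leading/trailing beats are
#' discarded; a record without detectable beats yields zero rows.
#'
#' @param wave A `waveform_set`.
#' @return Integer matrix with columns `start`, `end` (half-open
#'   `[start, end)`, 1-based sample indices), one row per complete beat.
#' @export
segment_beats <- function(wave) {
  vpg <- wave$vpg
  if (length(vpg) < wave$fs) stop_ppght("need at least 1 s of signal")
  empty <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  pk <- local_maxima(vpg)
  pk <- pk[vpg[pk] > 0]
  if (length(pk) == 0L) return(empty)
  # candidate systolic upslopes: anchor on the prominent peaks so that small
  # noise maxima cannot drag the median down, then apply the half-median rule
  cand <- pk[vpg[pk] >= 0.5 * max(vpg[pk])]
  pk <- pk[vpg[pk] >= 0.5 * stats::median(vpg[cand])]
  if (length(pk) < 2L) return(empty)
  # keep one upslope peak per beat: within a 0.25 s refractory window (well
  # under any plausible beat) keep the taller peak
  keep <- pk[1L]
  for (p in pk[-1L]) {
    last <- keep[length(keep)]
    if (p - last > 0.25 * wave$fs) keep <- c(keep, p)
    else if (vpg[p] > vpg[last]) keep[length(keep)] <- p
  }
  pk <- keep
  if (length(pk) < 2L) return(empty)
  ppg <- wave$ppg
  # the onset (pulse foot) sits just before the upslope: search a window of
  # 0.3 s before each kept peak so a flat diastolic tail cannot capture it
  onsets <- vapply(seq_along(pk), function(i) {
    lo <- max(if (i == 1L) 1L else pk[i - 1L], pk[i] - as.integer(0.3 * wave$fs))
    seg <- ppg[lo:pk[i]]
    lo + which.min(seg) - 1L
  }, 0L)
  onsets <- unique(onsets)
  if (length(onsets) < 2L) return(empty)
  out <- cbind(start = onsets[-length(onsets)], end = onsets[-1L])
  out[out[, 2L] - out[, 1L] >= 0.3 * wave$fs, , drop = FALSE]
}

#' Detect the APG a--e waves in one beat
#'
#' a = first APG local maximum after the beat start, b = first minimum after
#' a, then c, d, e as the next alternating maximum/minimum/maximum before 80%
#' of the beat. Unfound landmarks are `NA`.
#'
#' @param wave A `waveform_set`.
#' @param beat Length-2 vector `(start, end)`.
#' @return Named integer vector `t_a, t_b, t_c, t_d, t_e`.
#' @export
detect_apg_points <- function(wave, beat) {
  s <- beat[1L]; e <- beat[2L]
  apg <- wave$apg
  lim <- s + floor(0.8 * (e - s))
  seg <- apg[s:(e - 1L)]
  zz <- zigzag_extrema(apg, s, e, delta = 0.02 * diff(range(seg)))
  mx <- zz$i[zz$type == "max"]; mn <- zz$i[zz$type == "min"]
  # a is the dominant early acceleration peak; require at least 60% of the
  # beat's APG maximum so edge noise cannot pre-empt it
  t_a <- first_after(mx[apg[mx] >= 0.6 * max(seg)], s - 1L)
  t_b <- if (is.na(t_a)) NA_integer_ else first_after(mn, t_a)
  t_c <- if (is.na(t_b)) NA_integer_ else first_after(mx, t_b)
  t_d <- if (is.na(t_c)) NA_integer_ else first_after(mn, t_c)
  t_e <- if (is.na(t_d)) NA_integer_ else first_after(mx, t_d)
  out <- c(t_a = t_a, t_b = t_b, t_c = t_c, t_d = t_d, t_e = t_e)
  out[!is.na(out) & out >= lim & !names(out) %in% c("t_a", "t_b")] <- NA_integer_
  out
}

#' Detect the VPG w/x/y/z waves in one beat
#'
#' w = global VPG maximum in the beat (the steepest systolic upslope), then
#' x, y, z as the next alternating local minimum/maximum/minimum.
#'
#' @inheritParams detect_apg_points
#' @return Named integer vector `t_w, t_x, t_y, t_z`.
#' @export
detect_vpg_points <- function(wave, beat) {
  s <- beat[1L]; e <- beat[2L]
  vpg <- wave$vpg
  t_w <- s + which.max(vpg[s:(e - 1L)]) - 1L
  seg <- vpg[s:(e - 1L)]
  zz <- zigzag_extrema(vpg, s, e, delta = 0.02 * diff(range(seg)))
  mx <- zz$i[zz$type == "max"]; mn <- zz$i[zz$type == "min"]
  t_x <- first_after(mn[vpg[mn] < 0], t_w)  # x is a genuine downslope trough
  t_y <- if (is.na(t_x)) NA_integer_ else first_after(mx, t_x)
  t_z <- if (is.na(t_y)) NA_integer_ else first_after(mn, t_y)
  c(t_w = t_w, t_x = t_x, t_y = t_y, t_z = t_z)
}

#' Detect the PPG O/S/N/D points in one beat
#'
#' O = beat-start minimum, S = global PPG maximum in the beat, N = first PPG
#' local minimum after S (falling back to the APG e-wave time for notchless
#' waveforms), D = first PPG local maximum after N.
#'
#' @inheritParams detect_apg_points
#' @param apg_points Output of [detect_apg_points()] (for the e-wave
#'   fallback); optional.
#' @return Named integer vector `t_O, t_S, t_N, t_D`.
#' @export
detect_ppg_points <- function(wave, beat, apg_points = NULL) {
  s <- beat[1L]; e <- beat[2L]
  ppg <- wave$ppg
  t_O <- s
  t_S <- s + which.max(ppg[s:(e - 1L)]) - 1L
  # notch = first prominence-filtered local minimum after S (>= 1% of the
  # pulse amplitude, so sub-noise wiggles are not notches) that is followed
  # by a diastolic rise; the pre-foot minimum of a notchless beat never is
  amp <- ppg[t_S] - ppg[t_O]
  zz <- zigzag_extrema(ppg, t_S, e, delta = 0.01 * amp)
  mn <- zz$i[zz$type == "min"]
  mn <- mn[vapply(mn, function(m) any(zz$i > m & zz$type == "max"), TRUE)]
  t_N <- if (length(mn)) mn[1L] else NA_integer_
  if (is.na(t_N) && !is.null(apg_points)) {
    te <- unname(apg_points["t_e"])
    if (!is.na(te) && te > t_S) t_N <- as.integer(te)
  }
  t_D <- NA_integer_
  if (!is.na(t_N)) {
    mx <- zz$i[zz$type == "max"]
    t_D <- first_after(mx, t_N)
  }
  c(t_O = t_O, t_S = t_S, t_N = t_N, t_D = t_D)
}

#' Delineate all fiducials of every complete beat in a record
#'
#' @param wave A `waveform_set`.
#' @return Data frame of class `beat_fiducials`, one row per beat, with
#'   `beat_start`, `beat_end` and the 13 landmark sample indices
#'   (`t_O ... t_e`, `NA` = missing).
#' @export
delineate <- function(wave) {
  beats <- segment_beats(wave)
  rows <- lapply(seq_len(nrow(beats)), function(i) {
    beat <- unname(beats[i, ])
    apg <- detect_apg_points(wave, beat)
    vpg <- detect_vpg_points(wave, beat)
    ppg <- detect_ppg_points(wave, beat, apg)
    as.data.frame(c(list(beat = i, beat_start = beat[[1L]], beat_end = beat[[2L]]),
                    as.list(ppg), as.list(vpg), as.list(apg)))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(integer(0), 0L, 17L)),
                    c("beat", "beat_start", "beat_end",
                      "t_O", "t_S", "t_N", "t_D", "t_w", "t_x", "t_y", "t_z",
                      "t_a", "t_b", "t_c", "t_d", "t_e"))
  class(out) <- c("beat_fiducials", class(out))
  out
}

#' Evaluate a landmark on a shifted waveform level
#'
#' Implements the level-projection notation of pulse-wave analysis: a
#' landmark's time can be read on a waveform above or below its native level,
#' e.g. `c-2` is the PPG value at the APG c-wave time and `S+1` is the VPG
#' value at the systolic peak time.
#'
#' @param wave A `waveform_set`.
#' @param landmark_time Sample index (may be `NA`).
#' @param native_level Landmark's native level (0 = PPG ... 3 = third
#'   derivative).
#' @param shift Level shift; `native_level + shift` must be in 0..3.
#' @return Waveform value, or `NA` for a missing landmark.
#' @export
project <- function(wave, landmark_time, native_level, shift = 0L) {
  lvl <- native_level + shift
  if (lvl < 0L || lvl > 3L) stop_ppght("projected level %d out of range 0..3", lvl)
  if (is.na(landmark_time)) return(NA_real_)
  wave_level(wave, lvl)[landmark_time]
}
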