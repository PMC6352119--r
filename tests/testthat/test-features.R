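# Catalogue structure and feature kernels.

test_that("catalogue has 125 uniquely named entries with the stated counts", {
  cl <- ppg_catalogue()
  expect_length(cl, 125L)
  nms <- vapply(cl, `[[`, "", "name")
  expect_identical(anyDuplicated(nms), 0L)
  counts <- catalogue_counts()
  expect_identical(as.integer(counts[c("time_span", "ppg_amplitude", "vpg_apg",
                                       "waveform_area", "power_area", "ratio", "slope")]),
                   c(23L, 14L, 10L, 4L, 15L, 43L, 16L))
})

test_that("field-notation lookup resolves the canonical exemplars", {
  hits <- ppg_feature_lookup(c("OS-", "SD-", "N/S", "c-1/w", "(b-c-d)/a",
                               "OS^/OO^", "S+1c-1}/O+1O+1}", "b-2d-2~"))
  expect_false(anyNA(hits))
  expect_true(is.na(ppg_feature_lookup("ZZ-")))
})

test_that("span / amplitude / ratio kernels do the stated arithmetic", {
  ws <- clean_wave()
  fid <- delineate(ws)
  r <- fid[2L, ]
  v <- evaluate_beat(ws, r)
  fs <- ws$fs
  expect_equal(v[["span_S_D"]], (r$t_D - r$t_S) / fs * 1000)
  expect_equal(v[["span_O_O2"]], (r$beat_end - r$beat_start) / fs * 1000)
  base <- ws$ppg[r$t_O]
  expect_equal(v[["amp_S"]], ws$ppg[r$t_S] - base)
  expect_equal(v[["amp_N__over__amp_S"]],
               (ws$ppg[r$t_N] - base) / (ws$ppg[r$t_S] - base))
  expect_equal(v[["amp_a-2"]], ws$ppg[r$t_a] - base)
  expect_equal(v[["span_O_S__over__span_O_O2"]], v[["span_O_S"]] / v[["span_O_O2"]])
  # worked ratio example: 250 ms crest time in an 800 ms beat
  expect_equal(250 / 800, 0.3125)
  # APG combination on its printed form
  a <- ws$apg[r$t_a]; b <- ws$apg[r$t_b]; cc <- ws$apg[r$t_c]; d <- ws$apg[r$t_d]
  expect_equal(v[["comb_b-c-d__over__a"]], (b - cc - d) / a)
})

test_that("curve areas match the closed-form erf oracle within 1%", {
  p <- make_params()
  period <- 0.8; fs <- 1000
  ws <- clean_wave(p, period, fs)
  fid <- delineate(ws)
  r <- fid[2L, ]
  v <- evaluate_beat(ws, r)
  rel <- function(i) {
    r <- ((i - 1L) %% round(period * fs)) / fs
    if (r > period / 2) r - period else r  # onsets may sit 1 sample before the wrap
  }
  base <- ws$ppg[r$t_O]
  oracle <- beat_integral(rel(r$t_O), rel(r$t_S), p, period) -
    base * (rel(r$t_S) - rel(r$t_O))
  expect_lt(abs(v[["area_O_S"]] - oracle) / abs(oracle), 0.01)
})

test_that("power areas are closed-interval square sums with valid ratios", {
  ws <- clean_wave()
  fid <- delineate(ws)
  r <- fid[2L, ]
  v <- evaluate_beat(ws, r)
  seg <- ws$vpg[r$t_S:r$t_c]
  expect_equal(v[["pow_S+1_c-1"]], sum(seg^2))
  full <- ws$vpg[r$t_O:r$beat_end]
  expect_equal(v[["pow_O+1_O+1"]], sum(full^2))
  ratio <- v[["pow_S+1_c-1__over__pow_O+1_O+1"]]
  expect_true(ratio > 0 && ratio <= 1)
})

test_that("power-area sub-interval ratios stay in (0, 1] over 100 seeded beats", {
  set.seed(123)
  n_checked <- 0L
  for (i in 1:40) {
    prof <- sample_subject(sample(c("normotensive", "hypertensive"), 1L), "SX")
    rec <- synthesize_record(prof, 0)
    ws <- waveform_set(rec$samples, rec$fs)
    fid <- delineate(ws)
    for (j in seq_len(nrow(fid))) {
      v <- evaluate_beat(ws, fid[j, ])
      for (f in c("pow_S+1_c-1__over__pow_O+1_O+1", "pow_S+1_d-1__over__pow_O+1_O+1",
                  "pow_w_S+1__over__pow_O+1_O+1")) {
        if (!is.na(v[[f]])) {
          n_checked <- n_checked + 1L
          expect_true(v[[f]] > 0 && v[[f]] <= 1)
        }
      }
      if (!is.na(v[["slope_S_c-2"]])) expect_lt(v[["slope_S_c-2"]], 0)
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("slope kernel and missing propagation behave as stated", {
  ws <- clean_wave()
  fid <- delineate(ws)
  r <- fid[2L, ]
  v <- evaluate_beat(ws, r)
  base <- ws$ppg[r$t_O]
  expect_equal(v[["slope_O_S"]],
               (ws$ppg[r$t_S] - base) / ((r$t_S - r$t_O) / ws$fs))
  # missing landmark propagates as NA, not zero
  r2 <- r; r2$t_D <- NA_integer_
  v2 <- evaluate_beat(ws, r2)
  expect_true(is.na(v2[["span_S_D"]]) && is.na(v2[["amp_D"]]) && is.na(v2[["slope_S_D"]]))
})

test_that("feature vectors aggregate beats by the median", {
  ws <- clean_wave(n_beats = 4)  # 3 complete beats
  fid <- delineate(ws)
  expect_gte(nrow(fid), 3L)
  v <- extract_features(ws, fid)
  expect_length(v, 125L)
  one <- extract_features(ws, fid[2L, ])
  expect_equal(one[["span_O_S"]], evaluate_beat(ws, fid[2L, ])[["span_O_S"]])
  expect_equal(median(c(2, 4, 100)), 4)  # robustness convention
  ws0 <- waveform_set(rep(0.2, 2000), 1000, filter = FALSE)
  expect_warning(v0 <- extract_features(ws0), "no complete beats")
  expect_true(all(is.na(v0)))
})

test_that("scale equivariance: gain changes leave ratio features unchanged", {
  p <- make_params()
  beat <- synthesize_beat(p, 0.8, 1000)
  ws1 <- waveform_set(rep(beat, 3), 1000, filter = FALSE)
  ws2 <- waveform_set(rep(beat, 3) * 7.3, 1000, filter = FALSE)
  v1 <- extract_features(ws1); v2 <- extract_features(ws2)
  cl <- ppg_catalogue()
  cats <- vapply(cl, `[[`, "", "category")
  nms <- vapply(cl, `[[`, "", "name")
  ratios <- nms[cats == "ratio"]
  spans <- nms[cats == "time_span"]
  expect_equal(v1[ratios], v2[ratios], tolerance = 1e-9)
  expect_equal(v1[spans], v2[spans], tolerance = 1e-9)   # time features gain-invariant
  expect_equal(v2[["amp_S"]], 7.3 * v1[["amp_S"]], tolerance = 1e-9)
})

test_that("z-score normalization follows the sample-SD convention", {
  X <- matrix(c(1, 2, 3, 10, 10, 10), ncol = 2)
  colnames(X) <- c("f1", "f2")
  tab <- as_feature_table(X)
  expect_warning(norm <- normalize_features(tab), "zero-variance")
  expect_equal(norm$f1, c(-1, 0, 1))
  expect_equal(norm$f2, c(0, 0, 0))
  # idempotence on an already-normalized column
  suppressWarnings(norm2 <- normalize_features(norm))
  expect_equal(norm2$f1, norm$f1, tolerance = 1e-12)
  # fitted statistics reusable on held-out rows
  held <- as_feature_table(matrix(c(4, 10), 1, 2, dimnames = list(NULL, c("f1", "f2"))))
  out <- suppressWarnings(normalize_features(held, center = attr(norm, "center"),
                                             scale = attr(norm, "scale")))
  expect_equal(out$f1, 2)
})
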