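test_that("make_windows reproduces the canonical sliding-window layouts", {
  # EEG: 9 windows of 200 ms stepping 100 ms over the first 1000 ms
  w <- make_windows(256, 256, 200, 0.5, limit_ms = 1000)
  expect_equal(nrow(w), 9)
  expect_equal(w$start_ms, seq(0, 800, by = 100))
  expect_equal(w$end_ms, seq(200, 1000, by = 100))

  # EMG: 7 windows of 400 ms over 1500 ms, last truncated to 1200-1500
  w <- make_windows(384, 256, 400, 0.5, allow_truncated = TRUE)
  expect_equal(nrow(w), 7)
  expect_equal(w$start_ms[7], 1200)
  expect_equal(w$end_ms[7], 1500)
  expect_equal(w$end_ms[6], 1400)

  # window spanning the whole signal -> 1 window
  expect_equal(nrow(make_windows(256, 256, 1000, 0.5)), 1)
  # with truncation allowed, a remainder of at least one step is emitted ...
  wt <- make_windows(256, 256, 200, 0.5, allow_truncated = TRUE)
  expect_equal(nrow(wt), 10)
  expect_equal(wt$start_ms[10], 900)
  # ... but a remainder under one step is not (25% overlap: step 150,
  # remainder after the 750 ms start is 100 < 150)
  wu <- make_windows(256, 256, 200, 0.25, allow_truncated = TRUE)
  expect_equal(max(wu$end_ms), 950)
  expect_equal(nrow(wu), 6)
  expect_error(make_windows(100, 256, 1000), "longer than")
})

test_that("apply_taper ramps the edges and leaves the middle alone", {
  x <- rep(1, 100)
  expect_equal(apply_taper(x, 0), x)
  t10 <- apply_taper(x, 0.10)
  expect_equal(t10[1], 0)
  expect_equal(t10[100], 0)
  expect_equal(t10[11:90], x[11:90])  # middle 80% untouched
  expect_true(all(diff(t10[1:10]) > 0))  # monotone cosine ramp
})

test_that("filterbank log-amplitudes localize tones (FFT oracle) and are log-linear", {
  fs <- 256; n <- 256
  centers <- exp(seq(log(1), log(40), length.out = 8))
  # independent oracle: the FFT peak of the tone lies nearest bank 3's center
  f3 <- centers[3]
  x <- apply_taper(sin(2 * pi * f3 * (0:(n - 1)) / fs), 0.1)
  mag <- Mod(fft(x))[1:129]
  peak_hz <- (which.max(mag) - 1) * fs / n
  expect_equal(which.min(abs(centers - peak_hz)), 3)

  amps <- filterbank_log_amps(x, fs, 8, 1, 40)
  expect_equal(which.max(amps), 3)

  # zero signal floors at log(eps)
  expect_equal(filterbank_log_amps(numeric(n), fs, 8, 1, 40),
               rep(log(1e-10), 8))

  # scaling by 10 shifts every output by log(10)
  expect_equal(filterbank_log_amps(10 * x, fs, 8, 1, 40), amps + log(10),
               tolerance = 1e-6)

  expect_error(filterbank_log_amps(x, fs, 50, 1, 4), "resolvable")
})

test_that("window descriptors append the untapered RMS", {
  fs <- 256
  p <- feature_params("EEG")
  d <- window_descriptors(rep(3, 256), fs, p)
  expect_length(d, 9)
  expect_equal(unname(d[9]), 3)                   # RMS of constant c is |c|
  s <- sin(2 * pi * 8 * (0:255) / fs)
  expect_equal(unname(window_descriptors(s, fs, p)[9]), 1 / sqrt(2),
               tolerance = 0.01)
  expect_equal(unname(window_descriptors(numeric(64), fs, p)[9]), 0)
})

test_that("segment extras match construction and an FFT oracle", {
  fs <- 256; p <- feature_params("EEG")

  # impulse at sample k -> normalized position of the maximum
  x <- numeric(256); x[73] <- 1
  ex <- segment_extras(x, fs, p)
  expect_equal(unname(ex["pos_max"]), 72 / 255)

  # 10 Hz tone: centroid within 0.5 Hz of the oracle peak
  s <- sin(2 * pi * 10 * (0:255) / fs)
  ex <- segment_extras(s, fs, p)
  expect_lt(abs(ex[["centroid"]] - 10), 0.5)

  # constant signal: std 0 (the Hanning fade gives a tapered constant some
  # low-frequency energy, so the all-banks-at-floor case is the zero signal)
  ex0 <- segment_extras(rep(4, 256), fs, p)
  expect_equal(unname(ex0[["std"]]), 0)
  exz <- segment_extras(numeric(256), fs, p)
  expect_equal(unname(exz[c("centroid", "entropy", "std", "slope")]),
               c(0, 0, 0, 0))
})

test_that("per-channel feature counts match the canonical layouts", {
  # EEG: (1 + 9) x (8 + 1) + 6 = 96 per channel
  ep <- matrix(rnorm(3 * 308), 3, 308,
               dimnames = list(c("Fz", "Cz", "Pz"), NULL))
  t_ms <- seq(-200, by = 1000 / 256, length.out = 308)
  v <- extract_features(ep, feature_params("EEG"), t_ms, 256)
  expect_length(v, 3 * 96)

  # EMG: (1 + 7) x (10 + 1) + 6 = 94 per region
  em <- matrix(abs(rnorm(384)), 1, 384, dimnames = list("corrugator", NULL))
  t_emg <- seq(0, by = 1000 / 256, length.out = 384)
  ve <- extract_features(em, feature_params("EMG"), t_emg, 256)
  expect_length(ve, 94)

  # count formula holds for arbitrary parameters
  for (nb in c(4, 6)) for (wm in c(250, 500)) {
    p <- feature_params("EEG", window_ms = wm, n_banks = nb,
                        window_limit_ms = 1000)
    nw <- nrow(make_windows(308 - 52, 256, wm, 0.5, 1000))
    vv <- extract_features(ep, p, t_ms, 256)
    expect_length(vv, 3 * ((1 + nw) * (nb + 1) + 6))
  }

  # epoch too short for the canonical EEG layout errors informatively
  short <- ep[, 1:200]
  expect_error(extract_features(short, feature_params("EEG"),
                                t_ms[1:200], 256), "achievable")
  expect_true(all(is.finite(v)))
})

test_that("batched table extraction equals the per-instance path", {
  ep <- tiny_epochs(seed = 4, participants = 3, trials_per_cell = 2)
  inst <- relabel(ep, "novelty")
  ft <- extract_feature_table(inst)
  p <- feature_params("EEG")
  for (i in c(1, 5, nrow(inst$meta))) {
    v <- extract_features(inst$data[i, , ], p, inst$time_ms, inst$fs)
    expect_equal(unname(ft$X[i, ]), unname(v), tolerance = 1e-12)
  }
  expect_equal(colnames(ft$X)[1], "Fz|full|bank1")

  # permuting channel order permutes feature blocks (no cross-channel leak)
  perm <- select_channels(inst, c("Pz", "Fz", "Cz"))
  ftp <- extract_feature_table(perm)
  expect_equal(unname(ftp$X[, 1:96]),
               unname(ft$X[, which(grepl("^Pz\\|", colnames(ft$X)))]))
})
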