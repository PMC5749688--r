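test_that("emg_condition removes DC, tracks rectified amplitude, resamples", {
  # DC input: the 20 Hz high-pass edge kills it
  out <- emg_condition(rep(5, 1024), fs_in = 1024)
  expect_lt(mean(abs(out)) / 5, 0.01)

  # unit 50 Hz sine: smoothed rectified mean ~ 2/pi
  t <- (0:1023) / 1024
  out <- emg_condition(sin(2 * pi * 50 * t), fs_in = 1024)
  mid <- out[round(length(out) * 0.2):round(length(out) * 0.8)]
  expect_lt(abs(mean(mid) - 2 / pi) / (2 / pi), 0.10)
  expect_true(all(out >= 0))

  # resampling bookkeeping
  expect_length(emg_condition(rnorm(950), fs_in = 1000), round(950 * 256 / 1000))
  expect_length(emg_condition(rnorm(2048), fs_in = 1024), 512)

  expect_error(emg_condition(rnorm(100), fs_in = 512), "Nyquist")
})

test_that("baseline_correct subtracts the per-channel baseline mean", {
  t_ms <- seq(-100, 396, by = 1000 / 256)
  ep <- matrix(3, nrow = 2, ncol = length(t_ms))
  expect_true(all(baseline_correct(ep, c(-100, 0), t_ms) == 0))

  # zero-mean baseline leaves the epoch unchanged; constant shifts vanish
  base_idx <- t_ms >= -100 & t_ms < 0
  ep2 <- rbind(sin(seq_along(t_ms)), cos(seq_along(t_ms)))
  ep2[, base_idx] <- sweep(ep2[, base_idx], 1, rowMeans(ep2[, base_idx]))
  expect_equal(baseline_correct(ep2, c(-100, 0), t_ms), ep2)
  expect_equal(baseline_correct(ep2 + 7, c(-100, 0), t_ms),
               baseline_correct(ep2, c(-100, 0), t_ms))

  # idempotence
  once <- baseline_correct(ep2 + rnorm(1), c(-100, 0), t_ms)
  expect_equal(baseline_correct(once, c(-100, 0), t_ms), once)

  expect_error(baseline_correct(ep2, c(500, 600), t_ms), "no samples")
})

test_that("reject_eeg_epoch applies the four artifact rules per channel", {
  fs <- 256
  rules <- rejection_rules("study1")
  good <- matrix(10 * sin(2 * pi * 5 * (0:255) / fs), nrow = 1)

  r <- reject_eeg_epoch(good, rules, fs)
  expect_true(r$keep)
  expect_length(r$violated, 0)

  # 80 uV sample violates the 75 uV absolute rule
  spike <- good; spike[1, 100] <- 80
  r <- reject_eeg_epoch(spike, rules, fs)
  expect_false(r$keep)
  expect_true("max_abs" %in% r$violated)

  # >100 uV range without crossing 75 uV absolute
  swing <- matrix(c(rep(-60, 128), rep(55, 128)) +
                    0.6 * sin(2 * pi * 7 * (0:255) / fs), nrow = 1)
  r <- reject_eeg_epoch(swing, rules, fs)
  expect_true("max_range" %in% r$violated)

  # 156 ms flat stretch below 0.50 uV
  flat <- good; flat[1, 60:99] <- 0.1
  r <- reject_eeg_epoch(flat, rules, fs)
  expect_true("flat" %in% r$violated)

  # step > 50 uV between consecutive samples
  step <- good; step[1, 201] <- step[1, 200] + 60
  expect_true("max_step" %in% reject_eeg_epoch(step, rules, fs)$violated)

  # gambling-study variant: only the 110 uV absolute rule is enabled
  r2 <- rejection_rules("study2")
  expect_true(reject_eeg_epoch(spike, r2, fs)$keep)       # 80 < 110
  big <- good; big[1, 50] <- 120
  expect_equal(reject_eeg_epoch(big, r2, fs)$violated, "max_abs")
  expect_true(reject_eeg_epoch(flat, r2, fs)$keep)        # flat rule off

  # monotonicity: adding a violation to a kept epoch never yields keep
  for (i in 1:5) {
    ep <- matrix(5 * sin(2 * pi * i * (0:255) / fs), nrow = 1)
    stopifnot(reject_eeg_epoch(ep, rules, fs)$keep)
    ep[1, 30 + i] <- 90
    expect_false(reject_eeg_epoch(ep, rules, fs)$keep)
  }
})

test_that("reject_epochs filters a set and reports rejected trials", {
  ep <- tiny_epochs(seed = 2, scale = 4)
  ep$data[3, 1, 50] <- 500  # inject one gross artifact
  res <- reject_epochs(ep, rejection_rules("study1"))
  expect_equal(nrow(res$epochs$meta) + nrow(res$report), nrow(ep$meta))
  expect_true(any(grepl("max_abs", res$report$rules)))
})

test_that("reject_emg_outliers screens ranges against 2 x P75", {
  d <- emg_design(participants = 5, trials_per_cell = 2)
  ep <- generate_epochs(d, default_effects(d, scale = 1), quiet_noise(),
                        seed = 9)

  # identical trials: every range equals P75 < 2 x P75, nothing removed
  ident <- ep
  for (i in seq_len(nrow(ident$meta))) ident$data[i, , ] <- ep$data[1, , ]
  res <- reject_emg_outliers(ident)
  expect_equal(res$report$n_removed, 0)

  # one wild trial exceeds every muscle's threshold and is removed
  wild <- ep
  base <- max(apply(ep$data, c(1, 2), function(x) diff(range(x))))
  wild$data[7, , 200] <- wild$data[7, , 200] + 6 * base
  res <- reject_emg_outliers(wild)
  expect_true(any(res$report$removed$participant == ep$meta$participant[7] &
                    res$report$removed$trial == ep$meta$trial[7]))
  expect_equal(nrow(res$epochs$meta), nrow(ep$meta) - res$report$n_removed)

  # participant with >50% outlying trials loses all trials
  d2 <- emg_design(participants = 4, trials_per_cell = 2)  # 12 trials/pp
  ep2 <- generate_epochs(d2, default_effects(d2, scale = 1), quiet_noise(),
                         seed = 10)
  idx <- which(ep2$meta$participant == 2)
  big <- max(apply(ep2$data, c(1, 2), function(x) diff(range(x))))
  for (i in idx[1:8]) ep2$data[i, , 100] <- ep2$data[i, , 100] + 8 * big
  res2 <- reject_emg_outliers(ep2)
  expect_true(2 %in% res2$report$dropped_participants)
  expect_false(2 %in% res2$epochs$meta$participant)

  # removal is invariant to participant ordering
  perm <- order(-ep2$meta$participant, ep2$meta$trial)
  ep2p <- ep2
  ep2p$data <- ep2$data[perm, , , drop = FALSE]
  ep2p$meta <- ep2$meta[perm, ]; rownames(ep2p$meta) <- NULL
  res2p <- reject_emg_outliers(ep2p)
  expect_equal(res2p$report$n_removed, res2$report$n_removed)
  expect_equal(sort(res2p$report$dropped_participants),
               sort(res2$report$dropped_participants))

  # percentile undefined below 4 pooled trials
  small <- ep2
  small$data <- ep2$data[1:3, , , drop = FALSE]
  small$meta <- ep2$meta[1:3, ]
  expect_error(reject_emg_outliers(small), "fewer than 4")
  expect_error(reject_emg_outliers(tiny_epochs(seed = 1)), "not EMG")
})
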