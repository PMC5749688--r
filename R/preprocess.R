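# Signal conditioning, baseline correction and trial rejection.
#
# Filtering is zero-phase by construction: the squared magnitude response of
# a 4th-order Butterworth filter (i.e. the amplitude response of
# forward-backward Butterworth filtering) is applied in the frequency domain.
# This preserves component latencies exactly and needs no IIR recursion on
# the short, finite epochs handled here.

# |H(f)|^2 of an order-n Butterworth low/high-pass at corner fc.
butter_power <- function(f, fc, n, type = c("low", "high")) {
  type <- match.arg(type)
  if (type == "low") 1 / (1 + (f / fc)^(2 * n))
  else ifelse(f == 0, 0, 1 / (1 + (fc / f)^(2 * n)))
}

# Zero-phase frequency-domain filter of a vector or of matrix columns.
fft_filter <- function(x, fs, low = NULL, high = NULL, order = 4) {
  v <- is.null(dim(x))
  if (v) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided
  H <- rep(1, n)
  if (!is.null(low)) H <- H * butter_power(f, low, order, "high")   # cut below `low`
  if (!is.null(high)) H <- H * butter_power(f, high, order, "low")  # cut above `high`
  y <- Re(stats::mvfft(stats::mvfft(x) * H, inverse = TRUE)) / n
  if (v) drop(y) else y
}

#' Condition a raw EMG channel
#'
#' Band-pass 20-400 Hz, full-wave rectification, 40 Hz low-pass smoothing,
#' and downsampling to 256 Hz — the standard surface-EMG amplitude-envelope
#' chain. Filters are zero-phase 4th-order Butterworth responses.
#'
#' @param raw single-channel numeric signal.
#' @param fs_in input sampling rate; must be >= 800 Hz so the 400 Hz band
#'   edge is below Nyquist.
#' @param fs_out output rate, default 256 Hz.
#' @return non-negative conditioned signal of length
#'   `round(length(raw) * fs_out / fs_in)`.
#' @export
emg_condition <- function(raw, fs_in, fs_out = 256) {
  if (fs_in < 800)
    stop2("emg_condition: fs_in = ", fs_in, " Hz violates the Nyquist ",
          "requirement for the 400 Hz band edge (need fs_in >= 800 Hz)")
  bp <- fft_filter(raw, fs_in, low = 20, high = 400)
  sm <- fft_filter(abs(bp), fs_in, high = 40)
  n_out <- round(length(raw) * fs_out / fs_in)
  t_in <- (seq_along(raw) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  y <- stats::approx(t_in, sm, xout = pmin(t_out, max(t_in)))$y
  pmax(y, 0)  # smoothing ripple can dip microscopically below zero
}

#' Optional EEG conditioning for raw-mode inputs
#'
#' 0.1 Hz high-pass (24 dB/oct, order 4) and 30 Hz low-pass (48 dB/oct,
#' order 8), zero-phase. The packaged epoch generator emits band-limited
#' epochs already, so this is only needed for externally supplied raw
#' signals.
#'
#' @param x signal vector or samples x channels matrix.
#' @param fs sampling rate in Hz.
#' @return filtered signal, same shape.
#' @export
eeg_condition <- function(x, fs) {
  y <- fft_filter(x, fs, low = 0.1, order = 4)
  fft_filter(y, fs, high = 30, order = 8)
}

#' Baseline-correct an epoch (or every epoch of a set)
#'
#' Subtracts, per channel, the mean amplitude over the baseline window from
#' every sample. Idempotent; invariant to per-channel constant offsets.
#'
#' @param x channels x samples matrix, or an `epoch_set`.
#' @param baseline_window c(start_ms, end_ms); samples with
#'   start <= t < end are the baseline. Default -100..0 ms.
#' @param time_ms time axis (taken from the set when `x` is an `epoch_set`).
#' @return corrected object of the same shape.
#' @export
baseline_correct <- function(x, baseline_window = c(-100, 0), time_ms = NULL) {
  if (inherits(x, "epoch_set")) {
    idx <- baseline_idx(x$time_ms, baseline_window)
    bl <- apply(x$data[, , idx, drop = FALSE], c(1, 2), mean)
    x$data <- x$data - as.vector(bl)  # recycles over the sample dimension
    return(x)
  }
  stopifnot(is.matrix(x), !is.null(time_ms), length(time_ms) == ncol(x))
  idx <- baseline_idx(time_ms, baseline_window)
  x - rowMeans(x[, idx, drop = FALSE])
}

baseline_idx <- function(time_ms, win) {
  idx <- which(time_ms >= win[1] & time_ms < win[2])
  if (!length(idx))
    stop2("baseline_correct: baseline window [", win[1], ", ", win[2],
          ") ms contains no samples of the time axis")
  idx
}

#' EEG epoch artifact-rejection rules
#'
#' Default thresholds are the oddball-study set: absolute amplitude 75 uV,
#' within-segment range 100 uV, flat period (> 100 ms of activity below
#' 0.50 uV), and sample-to-sample step 50 uV. The gambling-study variant
#' enables only the absolute-amplitude rule at 110 uV
#' (`rejection_rules("study2")`).
#'
#' @param preset "study1" (all four rules) or "study2" (max_abs at 110 only).
#' @param max_abs_uV,max_range_uV,flat_window_ms,flat_threshold_uV,max_step_uV
#'   thresholds; all must be > 0.
#' @param enabled character subset of
#'   c("max_abs", "max_range", "flat", "max_step").
#' @return object of class `rejection_rules`.
#' @export
rejection_rules <- function(preset = c("study1", "study2"),
                            max_abs_uV = NULL, max_range_uV = 100,
                            flat_window_ms = 100, flat_threshold_uV = 0.50,
                            max_step_uV = 50, enabled = NULL) {
  preset <- match.arg(preset)
  if (preset == "study2") {
    max_abs_uV <- max_abs_uV %||% 110
    enabled <- enabled %||% "max_abs"
  } else {
    max_abs_uV <- max_abs_uV %||% 75
    enabled <- enabled %||% c("max_abs", "max_range", "flat", "max_step")
  }
  stopifnot(max_abs_uV > 0, max_range_uV > 0, flat_window_ms > 0,
            flat_threshold_uV > 0, max_step_uV > 0,
            all(enabled %in% c("max_abs", "max_range", "flat", "max_step")))
  structure(list(max_abs_uV = max_abs_uV, max_range_uV = max_range_uV,
                 flat_window_ms = flat_window_ms,
                 flat_threshold_uV = flat_threshold_uV,
                 max_step_uV = max_step_uV, enabled = enabled),
            class = "rejection_rules")
}

#' Test one EEG epoch against the artifact rules
#'
#' Rules are evaluated per channel; the epoch is rejected if any enabled rule
#' is violated on any channel (the strictest reading — flagged in rejection
#' reports). All violated rules are reported, not just the first.
#'
#' @param epoch channels x samples matrix (finite values).
#' @param rules a [rejection_rules()] object.
#' @param fs sampling rate in Hz (needed for the flat-period rule).
#' @return list with `keep` (logical) and `violated` (character vector of
#'   rule names, empty when kept).
#' @export
reject_eeg_epoch <- function(epoch, rules, fs) {
  stopifnot(is.matrix(epoch), all(is.finite(epoch)))
  violated <- character(0)
  en <- rules$enabled
  if ("max_abs" %in% en && any(abs(epoch) > rules$max_abs_uV))
    violated <- c(violated, "max_abs")
  if ("max_range" %in% en) {
    rng <- apply(epoch, 1, function(x) diff(range(x)))
    if (any(rng > rules$max_range_uV)) violated <- c(violated, "max_range")
  }
  if ("flat" %in% en) {
    flat <- apply(epoch, 1, function(x) {
      r <- rle(abs(x) < rules$flat_threshold_uV)
      any(r$values & r$lengths * 1000 / fs > rules$flat_window_ms)
    })
    if (any(flat)) violated <- c(violated, "flat")
  }
  if ("max_step" %in% en) {
    if (any(abs(t(diff(t(epoch)))) > rules$max_step_uV))
      violated <- c(violated, "max_step")
  }
  list(keep = length(violated) == 0L, violated = violated)
}

#' Apply artifact rejection to every epoch of a set
#'
#' @param epochs an `epoch_set`.
#' @param rules a [rejection_rules()] object.
#' @return list with `epochs` (filtered set) and `report` (data.frame:
#'   participant, trial, rules violated; one row per rejected epoch).
#' @export
reject_epochs <- function(epochs, rules) {
  stopifnot(inherits(epochs, "epoch_set"))
  res <- lapply(seq_len(nrow(epochs$meta)), function(i)
    reject_eeg_epoch(epochs$data[i, , , drop = TRUE], rules, epochs$fs))
  keep <- vapply(res, `[[`, logical(1), "keep")
  rej <- which(!keep)
  report <- data.frame(
    participant = epochs$meta$participant[rej],
    trial = epochs$meta$trial[rej],
    rules = vapply(res[rej], function(r) paste(r$violated, collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE)
  list(epochs = subset_epoch_set(epochs, keep), report = report)
}

subset_epoch_set <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$meta <- epochs$meta[keep, , drop = FALSE]
  rownames(epochs$meta) <- NULL
  epochs
}

#' EMG outlier-screening policy
#'
#' @param range_multiplier threshold = multiplier x P75 of per-trial ranges
#'   (default 2).
#' @param percentile percentile of the pooled range distribution (default 75;
#'   linear-interpolation definition, quantile type 7).
#' @param participant_drop_fraction participants with more than this fraction
#'   of their trials removed lose all trials (default 0.5).
#' @return object of class `emg_outlier_policy`.
#' @export
emg_outlier_policy <- function(range_multiplier = 2, percentile = 75,
                               participant_drop_fraction = 0.5) {
  stopifnot(range_multiplier > 0, percentile > 0, percentile < 100,
            participant_drop_fraction > 0, participant_drop_fraction <= 1)
  structure(list(range_multiplier = range_multiplier, percentile = percentile,
                 participant_drop_fraction = participant_drop_fraction),
            class = "emg_outlier_policy")
}

#' Screen EMG trials for outlying amplitude ranges
#'
#' Per muscle region, the threshold is `range_multiplier` times the P75 of
#' the per-trial whole-epoch amplitude ranges, pooled over all participants
#' and conditions. A trial is removed when its range in either the baseline
#' (t < 0) or the post-stimulus (t >= 0) segment exceeds the threshold of
#' any muscle. Participants with more than `participant_drop_fraction` of
#' their trials removed lose all trials.
#'
#' @param epochs an EMG `epoch_set` whose time axis identifies baseline
#'   (negative times) and post-stimulus segments.
#' @param policy an [emg_outlier_policy()].
#' @return list with `epochs` (filtered set) and `report` (thresholds per
#'   muscle, removed-trial table, dropped participants, percentile
#'   definition).
#' @export
reject_emg_outliers <- function(epochs, policy = emg_outlier_policy()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$design$modality != "EMG")
    stop2("reject_emg_outliers: epoch set is not EMG")
  n <- nrow(epochs$meta)
  if (n < 4)
    stop2("reject_emg_outliers: fewer than 4 pooled trials; the P",
          policy$percentile, " range threshold is undefined")
  base_idx <- which(epochs$time_ms < 0)
  post_idx <- which(epochs$time_ms >= 0)
  if (!length(base_idx) || !length(post_idx))
    stop2("reject_emg_outliers: time axis must contain both a baseline ",
          "(t < 0) and a post-stimulus (t >= 0) segment")
  muscles <- epochs$channel_labels
  rng_seg <- function(idx) {
    apply(epochs$data[, , idx, drop = FALSE], c(1, 2),
          function(x) diff(range(x)))
  }
  full_rng <- apply(epochs$data, c(1, 2), function(x) diff(range(x)))
  thresholds <- policy$range_multiplier *
    apply(full_rng, 2, stats::quantile, probs = policy$percentile / 100,
          type = 7, names = FALSE)
  names(thresholds) <- muscles
  base_rng <- rng_seg(base_idx)
  post_rng <- rng_seg(post_idx)
  over <- sweep(base_rng, 2, thresholds, ">") | sweep(post_rng, 2, thresholds, ">")
  out_trial <- rowSums(over) > 0
  removed <- data.frame(
    participant = epochs$meta$participant[out_trial],
    trial = epochs$meta$trial[out_trial],
    muscles = apply(over[out_trial, , drop = FALSE], 1,
                    function(r) paste(muscles[r], collapse = ",")),
    stringsAsFactors = FALSE)
  dropped <- c()
  for (pp in unique(epochs$meta$participant)) {
    idx <- epochs$meta$participant == pp
    if (mean(out_trial[idx]) > policy$participant_drop_fraction)
      dropped <- c(dropped, pp)
  }
  keep <- !out_trial & !(epochs$meta$participant %in% dropped)
  list(epochs = subset_epoch_set(epochs, keep),
       report = list(thresholds = thresholds, removed = removed,
                     dropped_participants = dropped,
                     n_removed = sum(!keep),
                     percentile_definition = "linear interpolation (quantile type 7)"))
}
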