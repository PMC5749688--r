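# Synthetic factorial EEG/EMG epoch generation.
#
# The generator emulates the structure the decoding protocol assumes: a
# factorial psychophysiology experiment (appraisal checks crossed into
# condition cells), ERP-like class-dependent components (P3/LPP-style
# Gaussian-in-time bumps with a scalp topography), 1/f^beta background
# activity, white sensor noise, per-participant gain and per-trial latency
# jitter. It makes no attempt at volume conduction, ocular artifacts or the
# original stimulus sequences.

#' Describe a factorial epoched-recording design
#'
#' @param study_label free-text label.
#' @param modality "EEG" or "EMG".
#' @param participants number of participants (>= 3, one per fold minimum).
#' @param checks named list: check name -> character vector of level names.
#'   Every condition cell is one level per check (full crossing).
#' @param trials_per_cell per-participant trial count per cell: either a
#'   single number or a named vector over cell ids (levels joined by "/").
#' @param sampling_rate Hz, default 256.
#' @param epoch_window c(start_ms, end_ms) relative to stimulus onset.
#'   EEG designs that need a baseline must start < 0; EMG may start at 0.
#' @param channel_labels ordered channel names (extended 10-20 labels for
#'   EEG; frontalis/corrugator/zygomaticus for EMG).
#' @return object of class `design_spec`.
#' @export
design_spec <- function(study_label, modality = c("EEG", "EMG"), participants,
                        checks, trials_per_cell,
                        sampling_rate = 256,
                        epoch_window = c(-200, 1000),
                        channel_labels) {
  modality <- match.arg(modality)
  stopifnot(is.list(checks), length(checks) >= 1, !is.null(names(checks)))
  if (participants < 3) stop2("design_spec: need >= 3 participants (one per fold)")
  if (any(vapply(checks, length, integer(1)) < 2))
    stop2("design_spec: every check needs >= 2 levels")
  if (anyDuplicated(channel_labels)) stop2("design_spec: duplicate channel labels")
  cells <- cell_table(checks)
  if (length(trials_per_cell) == 1L && is.null(names(trials_per_cell))) {
    trials_per_cell <- stats::setNames(rep(as.integer(trials_per_cell), nrow(cells)),
                                       cells$cell)
  } else {
    miss <- setdiff(cells$cell, names(trials_per_cell))
    if (length(miss)) stop2("design_spec: trials_per_cell missing cells: ",
                            paste(miss, collapse = ", "))
    trials_per_cell <- trials_per_cell[cells$cell]
  }
  if (any(trials_per_cell < 0)) stop2("design_spec: trials_per_cell must be >= 0")
  stopifnot(epoch_window[1] < epoch_window[2])
  structure(list(
    study_label = study_label, modality = modality,
    participants = as.integer(participants), checks = checks,
    trials_per_cell = trials_per_cell,
    sampling_rate = sampling_rate, epoch_window = epoch_window,
    channel_labels = as.character(channel_labels)
  ), class = "design_spec")
}

# Full crossing of check levels; cell id = levels joined by "/" in check order.
cell_table <- function(checks) {
  g <- expand.grid(rev(checks), stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(checks)), drop = FALSE]
  names(g) <- names(checks)
  g$cell <- apply(g[, names(checks), drop = FALSE], 1, paste, collapse = "/")
  g
}

#' Time axis of a design
#'
#' Millisecond value of each sample; samples are half-open windows and 0 ms is
#' stimulus onset (the first sample at or after onset has time 0).
#' @param design a `design_spec`.
#' @return numeric vector of ms values.
#' @export
design_time_axis <- function(design) {
  fs <- design$sampling_rate
  i0 <- ceiling(design$epoch_window[1] * fs / 1000)
  i1 <- ceiling(design$epoch_window[2] * fs / 1000) - 1
  (i0:i1) * 1000 / fs
}

#' Describe one class-dependent signal component
#'
#' A component is a Gaussian-in-time bump whose amplitude depends on the level
#' of one appraisal check (an ERP-like effect such as a P3 or late positive
#' potential modulation), spread over channels by a fixed topography.
#'
#' @param check name of the check this effect is driven by.
#' @param amplitude named numeric vector, one entry per level of the check
#'   (microvolts for EEG, rectified-EMG units for EMG). All-zero amplitudes
#'   give a null effect.
#' @param peak_latency_ms peak time per level (single number recycled).
#' @param temporal_sd_ms width of the Gaussian component.
#' @param channel_topography named weights per channel label (unitless);
#'   channels not named get weight 0.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(check, amplitude, peak_latency_ms, temporal_sd_ms,
                        channel_topography) {
  stopifnot(!is.null(names(amplitude)), !is.null(names(channel_topography)),
            temporal_sd_ms > 0)
  if (length(peak_latency_ms) == 1L)
    peak_latency_ms <- stats::setNames(rep(peak_latency_ms, length(amplitude)),
                                       names(amplitude))
  stopifnot(setequal(names(peak_latency_ms), names(amplitude)))
  structure(list(check = check, amplitude = amplitude,
                 peak_latency_ms = peak_latency_ms[names(amplitude)],
                 temporal_sd_ms = temporal_sd_ms,
                 channel_topography = channel_topography),
            class = "effect_spec")
}

#' Describe the noise model
#'
#' @param background_exponent beta of the 1/f^beta background spectrum (>= 0).
#' @param background_scale RMS of the background activity (microvolts).
#' @param white_sd white sensor-noise SD (microvolts).
#' @param participant_gain_sd spread of the multiplicative per-participant
#'   gain on the effect components (log-normal, sdlog = this value).
#' @param latency_jitter_sd_ms per-trial jitter of component peak latency,
#'   drawn once per trial and applied coherently to all channels.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(background_exponent = 1, background_scale = 10,
                       white_sd = 2, participant_gain_sd = 0.2,
                       latency_jitter_sd_ms = 20) {
  stopifnot(background_exponent >= 0, background_scale >= 0, white_sd >= 0,
            participant_gain_sd >= 0, latency_jitter_sd_ms >= 0)
  structure(list(background_exponent = background_exponent,
                 background_scale = background_scale, white_sd = white_sd,
                 participant_gain_sd = participant_gain_sd,
                 latency_jitter_sd_ms = latency_jitter_sd_ms),
            class = "noise_spec")
}

#' Waveform contributed by one effect at one level
#'
#' amplitude(level) x topography outer Gaussian(peak_latency, temporal_sd)
#' evaluated on the time axis.
#'
#' @param effect an `effect_spec`.
#' @param level level name (must exist in the effect).
#' @param time_ms time axis in ms.
#' @param channel_labels channel order for the output rows.
#' @param latency_shift_ms optional additive latency shift (trial jitter).
#' @return channels x samples matrix.
#' @export
effect_waveform <- function(effect, level, time_ms, channel_labels,
                            latency_shift_ms = 0) {
  if (!level %in% names(effect$amplitude))
    stop2("effect_waveform: unknown level '", level, "' for check '",
          effect$check, "' (levels: ",
          paste(names(effect$amplitude), collapse = ", "), ")")
  a <- effect$amplitude[[level]]
  topo <- effect$channel_topography[channel_labels]
  topo[is.na(topo)] <- 0
  mu <- effect$peak_latency_ms[[level]] + latency_shift_ms
  g <- exp(-0.5 * ((time_ms - mu) / effect$temporal_sd_ms)^2)
  m <- a * outer(unname(topo), g)
  rownames(m) <- channel_labels
  m
}

# 1/f^beta colored noise, one column per channel, scaled to RMS `scale`.
colored_noise <- function(n_samples, n_channels, beta, scale) {
  if (scale == 0) return(matrix(0, n_samples, n_channels))
  w <- matrix(rnorm(n_samples * n_channels), n_samples, n_channels)
  if (beta == 0) return(scale * w)
  W <- stats::mvfft(w)
  f <- c(0, pmin(seq_len(n_samples - 1), n_samples - seq_len(n_samples - 1)))
  shape <- c(0, f[-1]^(-beta / 2))  # kill DC
  X <- Re(stats::mvfft(W * shape, inverse = TRUE)) / n_samples
  rms <- sqrt(colMeans(X^2))
  rms[rms == 0] <- 1
  sweep(X, 2, scale / rms, "*")
}

#' Generate a synthetic epoch set
#'
#' Per trial, epoch = participant gain x sum over checks of the effect
#' waveform at the trial's cell level (with per-trial latency jitter) +
#' 1/f background + white noise. EMG designs are generated directly as
#' non-negative rectified-style signals (|background| + |white| + burst).
#' Deterministic given the seed.
#'
#' @param design a `design_spec`.
#' @param effects list of `effect_spec`s; each must reference a check of the
#'   design and only declared levels.
#' @param noise a `noise_spec`.
#' @param seed integer seed; all randomness flows from it.
#' @return object of class `epoch_set` with fields `design`, `data`
#'   (trials x channels x samples array), `meta` (data.frame: participant,
#'   trial, cell), `channel_labels`, `time_ms`, `fs`.
#' @export
generate_epochs <- function(design, effects = list(), noise = noise_spec(),
                            seed = 1L) {
  stopifnot(inherits(design, "design_spec"), inherits(noise, "noise_spec"))
  for (e in effects) {
    if (!e$check %in% names(design$checks))
      stop2("generate_epochs: effect references unknown check '", e$check, "'")
    if (!setequal(names(e$amplitude), design$checks[[e$check]]))
      stop2("generate_epochs: effect levels for '", e$check,
            "' do not match the design levels")
    unknown <- setdiff(names(e$channel_topography), design$channel_labels)
    if (length(unknown))
      stop2("generate_epochs: effect topography names channels absent from ",
            "the design: ", paste(unknown, collapse = ", "))
  }
  time_ms <- design_time_axis(design)
  n_samp <- length(time_ms)
  chans <- design$channel_labels
  n_ch <- length(chans)
  cells <- cell_table(design$checks)
  per_pp <- sum(design$trials_per_cell)
  n_total <- design$participants * per_pp
  emg <- design$modality == "EMG"

  data <- array(0, dim = c(n_total, n_ch, n_samp),
                dimnames = list(NULL, chans, NULL))
  meta <- data.frame(participant = integer(n_total), trial = integer(n_total),
                     cell = character(n_total), stringsAsFactors = FALSE)

  with_seed(seed, {
    row <- 0L
    for (pp in seq_len(design$participants)) {
      gain <- exp(rnorm(1, 0, noise$participant_gain_sd))
      trial_in_pp <- 0L
      for (ci in seq_len(nrow(cells))) {
        cell_id <- cells$cell[ci]
        for (tr in seq_len(design$trials_per_cell[[cell_id]])) {
          row <- row + 1L
          trial_in_pp <- trial_in_pp + 1L
          jitter <- rnorm(1, 0, noise$latency_jitter_sd_ms)
          comp <- matrix(0, n_ch, n_samp)
          for (e in effects) {
            lvl <- cells[[e$check]][ci]
            comp <- comp + effect_waveform(e, lvl, time_ms, chans, jitter)
          }
          bg <- t(colored_noise(n_samp, n_ch, noise$background_exponent,
                                noise$background_scale))
          wn <- matrix(rnorm(n_ch * n_samp, 0, noise$white_sd), n_ch, n_samp)
          epoch <- if (emg) gain * comp + abs(bg) + abs(wn)
                   else gain * comp + bg + wn
          data[row, , ] <- epoch
          meta$participant[row] <- pp
          meta$trial[row] <- trial_in_pp
          meta$cell[row] <- cell_id
        }
      }
    }
  })
  new_epoch_set(design, data, meta, time_ms)
}

new_epoch_set <- function(design, data, meta, time_ms) {
  structure(list(design = design, data = data, meta = meta,
                 channel_labels = dimnames(data)[[2]],
                 time_ms = time_ms, fs = design$sampling_rate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set '%s' (%s): %d epochs, %d participants, %d channels, %d samples @%g Hz\n",
              x$design$study_label, x$design$modality, nrow(x$meta),
              length(unique(x$meta$participant)),
              length(x$channel_labels), length(x$time_ms), x$fs))
  invisible(x)
}

#' Bandlimited oscillatory raw EMG ("raw mode")
#'
#' Emits a single-channel 1024 Hz raw surface-EMG-like signal: white noise
#' bandlimited to 20-400 Hz, amplitude-modulated by an optional burst
#' envelope. Intended for exercising [emg_condition()]; the default epoch
#' generator emits already-conditioned (rectified-style) EMG.
#'
#' @param duration_ms signal length in ms.
#' @param fs sampling rate, default 1024 Hz.
#' @param burst optional list(onset_ms, duration_ms, gain) multiplying the
#'   baseline activity during the burst.
#' @param seed integer seed.
#' @return numeric vector of length round(duration_ms * fs / 1000).
#' @export
raw_emg_signal <- function(duration_ms, fs = 1024, burst = NULL, seed = 1L) {
  n <- round(duration_ms * fs / 1000)
  with_seed(seed, {
    x <- rnorm(n)
    X <- fft(x)
    f <- (seq_len(n) - 1) * fs / n
    f <- pmin(f, fs - f)
    keep <- f >= 20 & f <= 400
    X[!keep] <- 0
    x <- Re(fft(X, inverse = TRUE)) / n
    x <- x / sd(x)
    if (!is.null(burst)) {
      t_ms <- (seq_len(n) - 1) * 1000 / fs
      env <- ifelse(t_ms >= burst$onset_ms &
                    t_ms < burst$onset_ms + burst$duration_ms, burst$gain, 1)
      x <- x * env
    }
    x
  })
}
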