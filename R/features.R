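# Static spectro-temporal feature extraction.
#
# Per channel the layout is: descriptors of the full post-stimulus segment,
# descriptors of each sliding window, then six full-segment extras. A
# descriptor block is n_banks log filter-bank amplitudes plus the RMS frame
# energy, so the per-channel count is (1 + n_windows) * (n_banks + 1) + 6:
# 96 for the canonical EEG layout (8 banks, 9 windows), 94 for EMG (10
# banks, 7 windows). Spectra are computed on the tapered segment; RMS and
# the time-domain extras on the untapered one.

FEATURE_EPS <- 1e-10

#' Feature-extraction parameters
#'
#' @param modality "EEG" or "EMG". EEG defaults: 200 ms windows, 50%
#'   overlap, windows limited to the first 1000 ms, 8 filter banks log-spaced
#'   on 1-40 Hz, no truncated final window. EMG defaults: 400 ms windows
#'   over the whole signal, 10 banks on 20-60 Hz, truncated final window
#'   allowed.
#' @param window_ms,overlap_fraction,window_limit_ms,n_banks,f_lo,f_hi,fade_fraction,allow_truncated
#'   overrides of the modality defaults. `window_limit_ms = NULL` means the
#'   windows run to the end of the post-stimulus signal.
#' @return object of class `feature_params`.
#' @export
feature_params <- function(modality = c("EEG", "EMG"), window_ms = NULL,
                           overlap_fraction = 0.5, window_limit_ms = NULL,
                           n_banks = NULL, f_lo = NULL, f_hi = NULL,
                           fade_fraction = 0.10, allow_truncated = NULL) {
  modality <- match.arg(modality)
  if (modality == "EEG") {
    window_ms <- window_ms %||% 200
    if (missing(window_limit_ms)) window_limit_ms <- 1000
    n_banks <- n_banks %||% 8; f_lo <- f_lo %||% 1; f_hi <- f_hi %||% 40
    allow_truncated <- allow_truncated %||% FALSE
  } else {
    window_ms <- window_ms %||% 400
    n_banks <- n_banks %||% 10; f_lo <- f_lo %||% 20; f_hi <- f_hi %||% 60
    allow_truncated <- allow_truncated %||% TRUE
  }
  stopifnot(f_lo > 0, f_lo < f_hi, overlap_fraction >= 0, overlap_fraction < 1,
            n_banks >= 2, fade_fraction >= 0, fade_fraction <= 0.5)
  structure(list(modality = modality, window_ms = window_ms,
                 overlap_fraction = overlap_fraction,
                 window_limit_ms = window_limit_ms, n_banks = n_banks,
                 f_lo = f_lo, f_hi = f_hi, fade_fraction = fade_fraction,
                 allow_truncated = allow_truncated),
            class = "feature_params")
}

#' Sliding-window layout
#'
#' Windows start at 0 ms (post-stimulus), step by
#' `window_ms * (1 - overlap_fraction)`, and stop at the limit (or the
#' signal end). A final truncated window is emitted only when
#' `allow_truncated` and at least one step of signal remains after the last
#' full window's start. Canonical layouts: 9 windows of 200 ms over 1000 ms
#' at 50% overlap (EEG); 7 windows of 400 ms over 1500 ms, the last
#' truncated to 1200-1500 ms (EMG).
#'
#' @param n_samples post-stimulus sample count.
#' @param fs sampling rate in Hz.
#' @param window_ms,overlap_fraction,limit_ms,allow_truncated see
#'   [feature_params()].
#' @return data.frame with `start_ms`, `end_ms` and half-open sample ranges
#'   as 1-based `start`/`end` column indices (inclusive).
#' @export
make_windows <- function(n_samples, fs, window_ms, overlap_fraction = 0.5,
                         limit_ms = NULL, allow_truncated = FALSE) {
  dur_ms <- n_samples * 1000 / fs
  limit <- min(limit_ms %||% dur_ms, dur_ms)
  if (window_ms > limit)
    stop2("make_windows: window (", window_ms, " ms) longer than the covered ",
          "signal (", limit, " ms)")
  step <- window_ms * (1 - overlap_fraction)
  starts <- seq(0, limit - window_ms, by = step)
  ends <- starts + window_ms
  nxt <- if (length(starts)) starts[length(starts)] + step else 0
  if (allow_truncated && (limit - nxt) >= step && nxt + window_ms > limit) {
    starts <- c(starts, nxt)
    ends <- c(ends, limit)
  }
  data.frame(start_ms = starts, end_ms = ends,
             start = round(starts * fs / 1000) + 1L,
             end = pmin(round(ends * fs / 1000), n_samples))
}

#' Apply a Hanning fade taper
#'
#' Raised-cosine ramps over the first and last `fade_fraction * length`
#' samples (a "rectangular window with 10% Hanning fade"); the middle is
#' untouched and the end samples go exactly to 0.
#'
#' @param x numeric vector, or a matrix tapered column-wise.
#' @param fade_fraction fraction of the length ramped at each end (0-0.5).
#' @return tapered object of the same shape.
#' @export
apply_taper <- function(x, fade_fraction = 0.10) {
  stopifnot(fade_fraction >= 0, fade_fraction <= 0.5)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  w <- taper_weights(n, fade_fraction)
  x * w
}

taper_weights <- function(n, fade_fraction) {
  w <- rep(1, n)
  k <- floor(fade_fraction * n)
  if (k >= 1) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(k) - 1) / k))
    w[seq_len(k)] <- ramp
    w[n + 1 - seq_len(k)] <- ramp
  }
  w
}

# One-sided magnitude spectrum; segments are zero-padded to the next power
# of two so short sliding windows still resolve the filter-bank band.
next_pow2 <- function(n) 2^ceiling(log2(n))

mag_spectrum <- function(x) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  nfft <- next_pow2(n)
  if (nfft > n) {
    if (is.matrix(x)) x <- rbind(x, matrix(0, nfft - n, ncol(x)))
    else x <- c(x, numeric(nfft - n))
  }
  nb <- nfft / 2 + 1L
  if (is.matrix(x)) Mod(stats::mvfft(x)[seq_len(nb), , drop = FALSE])
  else Mod(fft(x)[seq_len(nb)])
}

spectrum_freqs <- function(n, fs) {
  nfft <- next_pow2(n)
  (seq_len(nfft / 2 + 1L) - 1) * fs / nfft
}

# Triangular filter-bank weight matrix (n_banks x n_bins). Centers are
# log-spaced on [f_lo, f_hi]; each filter rises from the previous center and
# falls to the next; the end filters are extended flat to f_lo / f_hi.
bank_weights <- function(freqs, n_banks, f_lo, f_hi) {
  centers <- exp(seq(log(f_lo), log(f_hi), length.out = n_banks))
  in_band <- freqs >= f_lo & freqs <= f_hi
  if (sum(in_band) < n_banks)
    stop2("bank_weights: ", n_banks, " banks exceed the ", sum(in_band),
          " resolvable spectral bins in [", f_lo, ", ", f_hi, "] Hz")
  W <- matrix(0, n_banks, length(freqs))
  for (j in seq_len(n_banks)) {
    lo <- if (j == 1L) f_lo else centers[j - 1L]
    hi <- if (j == n_banks) f_hi else centers[j + 1L]
    c_ <- centers[j]
    rise <- if (c_ > lo) (freqs - lo) / (c_ - lo) else 1
    fall <- if (hi > c_) (hi - freqs) / (hi - c_) else 1
    w <- pmin(rise, fall)
    w[!in_band] <- 0
    W[j, ] <- pmin(pmax(w, 0), 1)
  }
  attr(W, "centers") <- centers
  W
}

#' Log filter-bank amplitudes of one (tapered) segment
#'
#' Triangular filters on the one-sided magnitude spectrum, center
#' frequencies log-spaced on `[f_lo, f_hi]`; output is the natural log of
#' the filtered amplitude sum plus a 1e-10 floor (so a zero signal maps to
#' `log(1e-10)` and scaling the signal by a shifts every output by log a).
#'
#' @param segment tapered signal segment (vector).
#' @param fs sampling rate.
#' @param n_banks,f_lo,f_hi bank layout.
#' @return numeric vector of `n_banks` log-amplitudes.
#' @export
filterbank_log_amps <- function(segment, fs, n_banks, f_lo, f_hi) {
  mag <- mag_spectrum(segment)
  freqs <- spectrum_freqs(length(segment), fs)
  W <- bank_weights(freqs, n_banks, f_lo, f_hi)
  log(as.vector(W %*% mag) + FEATURE_EPS)
}

#' Descriptor block of one window
#'
#' `n_banks` log filter-bank amplitudes of the tapered segment followed by
#' the RMS frame energy of the untapered segment.
#'
#' @param segment raw (untapered) signal segment.
#' @param fs sampling rate.
#' @param params a [feature_params()] object.
#' @return numeric vector of length `n_banks + 1`.
#' @export
window_descriptors <- function(segment, fs, params) {
  tapered <- apply_taper(segment, params$fade_fraction)
  c(filterbank_log_amps(tapered, fs, params$n_banks, params$f_lo, params$f_hi),
    sqrt(mean(segment^2)))
}

#' Six full-segment extras
#'
#' Spectral centroid over `[f_lo, f_hi]`, positions of the time-domain
#' minimum and maximum (sample index normalized to 0-1), spectral entropy
#' (natural log, magnitude spectrum restricted to the band), time-domain
#' standard deviation, and the least-squares slope of log bank amplitude
#' versus log bank center frequency. A zero spectrum yields centroid 0 and
#' entropy 0 by convention.
#'
#' @param segment raw full-length post-stimulus segment.
#' @param fs sampling rate.
#' @param params a [feature_params()] object.
#' @return named numeric 6-vector
#'   (centroid, pos_min, pos_max, entropy, std, slope).
#' @export
segment_extras <- function(segment, fs, params) {
  n <- length(segment)
  tapered <- apply_taper(segment, params$fade_fraction)
  mag <- mag_spectrum(tapered)
  freqs <- spectrum_freqs(n, fs)
  band <- freqs >= params$f_lo & freqs <= params$f_hi
  msum <- sum(mag[band])
  centroid <- if (msum > 0) sum(freqs[band] * mag[band]) / msum else 0
  p <- if (msum > 0) mag[band] / msum else NULL
  entropy <- if (is.null(p)) 0 else { p <- p[p > 0]; -sum(p * log(p)) }
  banks <- filterbank_log_amps(tapered, fs, params$n_banks,
                               params$f_lo, params$f_hi)
  lc <- log(attr(bank_weights(freqs, params$n_banks, params$f_lo,
                              params$f_hi), "centers"))
  lc_c <- lc - mean(lc)
  slope <- sum(lc_c * (banks - mean(banks))) / sum(lc_c^2)
  c(centroid = centroid,
    pos_min = (which.min(segment) - 1) / (n - 1),
    pos_max = (which.max(segment) - 1) / (n - 1),
    entropy = entropy,
    std = sd(segment),
    slope = slope)
}

# Post-stimulus segment layout shared by single and batched extraction.
feature_layout <- function(time_ms, fs, params) {
  post <- which(time_ms >= 0)
  if (!length(post)) stop2("extract_features: no post-stimulus samples")
  n_post <- length(post)
  post_ms <- n_post * 1000 / fs
  if (!is.null(params$window_limit_ms) && post_ms < params$window_limit_ms) {
    achievable <- nrow(make_windows(n_post, fs, params$window_ms,
                                    params$overlap_fraction, NULL,
                                    params$allow_truncated))
    stop2("extract_features: epoch has ", round(post_ms), " ms of ",
          "post-stimulus signal but the canonical layout needs ",
          params$window_limit_ms, " ms; only ", achievable,
          " sliding window(s) would be achievable")
  }
  wins <- make_windows(n_post, fs, params$window_ms, params$overlap_fraction,
                       params$window_limit_ms, params$allow_truncated)
  list(post = post, windows = wins,
       n_features = (1L + nrow(wins)) * (params$n_banks + 1L) + 6L)
}

feature_names_one <- function(ch, layout, params) {
  bank <- paste0("bank", seq_len(params$n_banks))
  blocks <- c("full", sprintf("w%02d", seq_len(nrow(layout$windows))))
  c(as.vector(vapply(blocks, function(b) paste(ch, b, c(bank, "rms"), sep = "|"),
                     character(params$n_banks + 1L))),
    paste(ch, "extras",
          c("centroid", "pos_min", "pos_max", "entropy", "std", "slope"),
          sep = "|"))
}

#' Extract the static feature vector of one instance epoch
#'
#' Per channel: descriptors of the full post-stimulus segment, descriptors
#' of each sliding window, then the six extras; channels concatenated in
#' channel order with deterministic column names `channel|block|descriptor`.
#' The canonical EEG parameters yield 96 features per channel
#' ((1 + 9) x (8 + 1) + 6) and the EMG parameters 94 ((1 + 7) x (10 + 1) + 6).
#'
#' @param epoch channels x samples matrix.
#' @param params a [feature_params()] object.
#' @param time_ms time axis of the epoch (ms, 0 = stimulus onset).
#' @param fs sampling rate.
#' @return named numeric feature vector.
#' @export
extract_features <- function(epoch, params, time_ms, fs) {
  stopifnot(is.matrix(epoch), length(time_ms) == ncol(epoch))
  layout <- feature_layout(time_ms, fs, params)
  chans <- rownames(epoch) %||% paste0("ch", seq_len(nrow(epoch)))
  out <- lapply(seq_len(nrow(epoch)), function(ci) {
    x <- epoch[ci, layout$post]
    segs <- c(list(x), lapply(seq_len(nrow(layout$windows)), function(w)
      x[layout$windows$start[w]:layout$windows$end[w]]))
    c(unlist(lapply(segs, window_descriptors, fs = fs, params = params)),
      segment_extras(x, fs, params))
  })
  v <- unlist(out)
  names(v) <- as.vector(vapply(chans, feature_names_one,
                               character(layout$n_features),
                               layout = layout, params = params))
  v
}

#' Extract a feature table from an instance set (batched)
#'
#' Vectorized equivalent of calling [extract_features()] on every instance:
#' all segments of a kind are Fourier-transformed in one batch, which makes
#' whole-set extraction fast enough for simulation studies. The result is
#' bit-identical to the per-instance path up to floating-point reassociation.
#'
#' @param x an `instance_set`.
#' @param params a [feature_params()] object; defaults to the modality's
#'   canonical parameters.
#' @return object of class `feature_table`: `X` (instances x features matrix
#'   with deterministic column names), `meta` (participant, label), `check`,
#'   `n_averaged`, `params`.
#' @export
extract_feature_table <- function(x, params = NULL) {
  stopifnot(inherits(x, "instance_set"))
  params <- params %||% feature_params(x$modality %||% "EEG")
  fs <- x$fs
  layout <- feature_layout(x$time_ms, fs, params)
  n_inst <- dim(x$data)[1]
  n_ch <- dim(x$data)[2]
  chans <- x$channel_labels
  nW <- nrow(layout$windows)
  nb <- params$n_banks
  per_ch <- layout$n_features

  # [samples, ch, inst] post-stimulus cube; columns of M are (ch, inst) pairs
  cube <- aperm(x$data[, , layout$post, drop = FALSE], c(3, 2, 1))
  ncol_flat <- n_ch * n_inst

  seg_ranges <- rbind(c(1L, length(layout$post)),
                      cbind(layout$windows$start, layout$windows$end))
  feats <- array(0, dim = c(per_ch, n_ch, n_inst))

  for (s in seq_len(nrow(seg_ranges))) {
    idx <- seg_ranges[s, 1]:seg_ranges[s, 2]
    M <- cube[idx, , , drop = FALSE]
    dim(M) <- c(length(idx), ncol_flat)
    rms <- sqrt(colMeans(M^2))
    Mt <- M * taper_weights(length(idx), params$fade_fraction)
    mag <- mag_spectrum(Mt)
    freqs <- spectrum_freqs(length(idx), fs)
    W <- bank_weights(freqs, nb, params$f_lo, params$f_hi)
    B <- log(W %*% mag + FEATURE_EPS)  # nb x ncol_flat
    rows <- ((s - 1L) * (nb + 1L) + 1L):(s * (nb + 1L))
    feats[rows, , ] <- rbind(B, rms)

    if (s == 1L) {  # full-segment extras
      band <- freqs >= params$f_lo & freqs <= params$f_hi
      magb <- mag[band, , drop = FALSE]
      msum <- colSums(magb)
      centroid <- ifelse(msum > 0, colSums(freqs[band] * magb) / msum, 0)
      P <- sweep(magb, 2, ifelse(msum > 0, msum, 1), "/")
      PL <- P * log(P); PL[!is.finite(PL)] <- 0
      entropy <- ifelse(msum > 0, -colSums(PL), 0)
      n <- length(idx)
      pos_min <- (apply(M, 2, which.min) - 1) / (n - 1)
      pos_max <- (apply(M, 2, which.max) - 1) / (n - 1)
      mu <- colMeans(M)
      std <- sqrt(pmax(colMeans(M^2) - mu^2, 0) * n / (n - 1))
      lc <- log(attr(W, "centers")); lc_c <- lc - mean(lc)
      slope <- as.vector(crossprod(B - rep(colMeans(B), each = nb), lc_c)) /
        sum(lc_c^2)
      ex_rows <- (per_ch - 5L):per_ch
      feats[ex_rows, , ] <- rbind(centroid, pos_min, pos_max, entropy,
                                  std, slope)
    }
  }
  X <- matrix(aperm(feats, c(1, 2, 3)), nrow = n_inst, ncol = per_ch * n_ch,
              byrow = TRUE)
  colnames(X) <- as.vector(vapply(chans, feature_names_one,
                                  character(per_ch),
                                  layout = layout, params = params))
  structure(list(X = X, meta = x$meta[, c("participant", "label")],
                 check = x$check, levels = x$levels,
                 n_averaged = x$n_averaged, params = params,
                 channel_labels = chans),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d instances x %d features (%d channels x %d), check '%s'\n",
              nrow(x$X), ncol(x$X), length(x$channel_labels),
              ncol(x$X) / length(x$channel_labels), x$check))
  invisible(x)
}
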