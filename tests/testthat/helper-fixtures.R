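# Shared fixtures: tiny designs and hand-built sets, constructed in code.

tiny_design <- function(participants = 4, trials_per_cell = 3,
                        channels = c("Fz", "Cz", "Pz"),
                        epoch_window = c(-200, 1000)) {
  binary_design(participants = participants,
                trials_per_cell = trials_per_cell,
                channel_labels = channels, epoch_window = epoch_window)
}

quiet_noise <- function() {
  noise_spec(background_exponent = 1, background_scale = 2, white_sd = 0.5,
             participant_gain_sd = 0.1, latency_jitter_sd_ms = 5)
}

tiny_epochs <- function(seed = 1, scale = 10, ...) {
  d <- tiny_design(...)
  baseline_correct(generate_epochs(d, default_effects(d, scale = scale),
                                   quiet_noise(), seed = seed))
}

# Instance set wrapping explicit epoch matrices (list of channels x samples),
# for feature tests that need exact signals.
manual_instances <- function(mats, fs = 256, t0_ms = 0,
                             labels = rep("a", length(mats)),
                             participants = seq_along(mats),
                             channel_labels = NULL) {
  n_ch <- nrow(mats[[1]])
  n_samp <- ncol(mats[[1]])
  channel_labels <- channel_labels %||% paste0("ch", seq_len(n_ch))
  data <- array(0, dim = c(length(mats), n_ch, n_samp),
                dimnames = list(NULL, channel_labels, NULL))
  for (i in seq_along(mats)) data[i, , ] <- mats[[i]]
  structure(list(data = data,
                 meta = data.frame(participant = participants, label = labels,
                                   cell = labels, stringsAsFactors = FALSE),
                 check = "manual", levels = unique(labels), n_averaged = 1L,
                 modality = "EEG", channel_labels = channel_labels,
                 time_ms = (seq_len(n_samp) - 1) * 1000 / fs + t0_ms,
                 fs = fs),
            class = "instance_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
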