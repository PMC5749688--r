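# Packaged designs mirroring the two source studies at reduced trial counts.

#' Standard 64-channel extended 10-20 montage (Biosemi ordering)
#' @return character vector of 64 channel labels.
#' @export
biosemi64_labels <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
}

#' Packaged oddball-style design ("study1")
#'
#' 25 participants, 2 novelty x 3 intrinsic-pleasantness cells, novelty
#' unbalanced ~1:3.5 (novel:familiar), 64-channel EEG at 256 Hz. Trial counts
#' are reduced relative to the source recordings (which held hundreds of
#' trials per participant) so the design is generatable at desk scale; the
#' cell structure and imbalance ratio are preserved. Epochs span -200..+1000
#' ms so the canonical feature layout (sliding windows over the first
#' 1000 ms) applies.
#'
#' @param participants default 25.
#' @param trials_novel per-cell per-participant trials for novel cells
#'   (default 2).
#' @param trials_familiar for familiar cells (default 7; 2:7 = 1:3.5).
#' @param channel_labels defaults to the full 64-channel montage.
#' @return a `design_spec`.
#' @export
study1_design <- function(participants = 25, trials_novel = 2,
                          trials_familiar = 7,
                          channel_labels = biosemi64_labels()) {
  checks <- list(novelty = c("novel", "familiar"),
                 pleasantness = c("unpleasant", "neutral", "pleasant"))
  cells <- cell_table(checks)
  tpc <- ifelse(cells$novelty == "novel", trials_novel, trials_familiar)
  names(tpc) <- cells$cell
  design_spec("study1", "EEG", participants, checks, tpc,
              sampling_rate = 256, epoch_window = c(-200, 1000),
              channel_labels = channel_labels)
}

#' Packaged gambling-style design ("study2")
#'
#' 24 participants, 2 x 2 x 2 goal-conduciveness x control x power cells,
#' control unbalanced ~1:3 (low:high), 64-channel EEG at 256 Hz, epochs
#' -200..+1500 ms. Trial counts reduced as in [study1_design()].
#'
#' @param participants default 24.
#' @param trials_control_low per-cell trials for control = low (default 2).
#' @param trials_control_high for control = high (default 6; 1:3).
#' @param channel_labels defaults to the full 64-channel montage.
#' @return a `design_spec`.
#' @export
study2_design <- function(participants = 24, trials_control_low = 2,
                          trials_control_high = 6,
                          channel_labels = biosemi64_labels()) {
  checks <- list(goal_conduciveness = c("high", "low"),
                 control = c("high", "low"),
                 power = c("high", "low"))
  cells <- cell_table(checks)
  tpc <- ifelse(cells$control == "low", trials_control_low,
                trials_control_high)
  names(tpc) <- cells$cell
  design_spec("study2", "EEG", participants, checks, tpc,
              sampling_rate = 256, epoch_window = c(-200, 1500),
              channel_labels = channel_labels)
}

#' Packaged EMG design
#'
#' Three bipolar muscle regions at 256 Hz, epochs 0..1500 ms (a separate
#' 100 ms baseline segment precedes stimulus onset so outlier screening can
#' inspect both segments), factorial structure as in the oddball study.
#'
#' @param participants default 25.
#' @param trials_per_cell default 4.
#' @return a `design_spec`.
#' @export
emg_design <- function(participants = 25, trials_per_cell = 4) {
  design_spec("study1-emg", "EMG", participants,
              checks = list(novelty = c("novel", "familiar"),
                            pleasantness = c("unpleasant", "neutral", "pleasant")),
              trials_per_cell = trials_per_cell,
              sampling_rate = 256, epoch_window = c(-100, 1500),
              channel_labels = c("frontalis", "corrugator", "zygomaticus"))
}

#' A small binary design for simulation studies
#'
#' Single check with two balanced levels; used by the package's own
#' calibration and recovery tests at reduced scale (defaults: 12
#' participants, 60 trials per cell, 8 midline-ish channels).
#'
#' @param participants,trials_per_cell,channel_labels,epoch_window see
#'   [design_spec()].
#' @param check_name,levels the single check.
#' @return a `design_spec`.
#' @export
binary_design <- function(participants = 12, trials_per_cell = 60,
                          channel_labels = c("Fz", "FCz", "Cz", "CPz", "Pz",
                                             "POz", "Oz", "AFz"),
                          epoch_window = c(-200, 1000),
                          check_name = "novelty",
                          levels = c("novel", "familiar")) {
  checks <- stats::setNames(list(levels), check_name)
  design_spec("binary-sim", "EEG", participants, checks, trials_per_cell,
              sampling_rate = 256, epoch_window = epoch_window,
              channel_labels = channel_labels)
}

#' Default ERP-like effects for a design
#'
#' One Gaussian component per check: a centro-parietal positivity whose
#' amplitude differs between levels (P3/late-positive-potential style). The
#' `scale` argument sets the between-level amplitude difference in microvolts
#' (or rectified-EMG units); `scale = 0` gives null effects.
#'
#' @param design a `design_spec`.
#' @param scale amplitude separation between successive levels (default 6).
#' @param peak_latency_ms component peak (default 400 ms).
#' @param temporal_sd_ms component width (default 80 ms).
#' @return list of `effect_spec`s, one per check.
#' @export
default_effects <- function(design, scale = 6, peak_latency_ms = 400,
                            temporal_sd_ms = 80) {
  chans <- design$channel_labels
  # centro-parietal emphasis when standard labels are present, flat otherwise
  topo <- stats::setNames(rep(0.5, length(chans)), chans)
  emph <- intersect(c("Cz", "CPz", "Pz", "POz", "C1", "C2", "CP1", "CP2",
                      "P1", "P2", "corrugator", "zygomaticus", "frontalis"),
                    chans)
  topo[emph] <- 1
  lapply(names(design$checks), function(ck) {
    lv <- design$checks[[ck]]
    amp <- stats::setNames(scale * (seq_along(lv) - 1), lv)
    effect_spec(ck, amplitude = amp, peak_latency_ms = peak_latency_ms,
                temporal_sd_ms = temporal_sd_ms, channel_topography = topo)
  })
}
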