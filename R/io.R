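# Plain-text hierarchical container for epoch and instance sets.
#
# Layout of an epoch-set directory:
#   meta.json              design, channel labels, time axis, sampling rate
#   manifest.tsv           participant, trial, cell, file (one row per epoch)
#   data/p<participant>/e<index>.tsv   channels x samples matrix, tab-separated
#
# Everything is text so containers diff, version and ship cleanly.

#' Write an epoch set to a directory container
#'
#' @param epochs an `epoch_set`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)
  d <- epochs$design
  meta <- list(study_label = d$study_label, modality = d$modality,
               participants = d$participants, checks = d$checks,
               trials_per_cell = as.list(d$trials_per_cell),
               sampling_rate = d$sampling_rate,
               epoch_window = d$epoch_window,
               channel_labels = d$channel_labels,
               time_ms = epochs$time_ms)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- character(nrow(epochs$meta))
  for (i in seq_len(nrow(epochs$meta))) {
    pp <- epochs$meta$participant[i]
    pdir <- file.path(dir, "data", paste0("p", pp))
    if (!dir.exists(pdir)) dir.create(pdir)
    files[i] <- file.path("data", paste0("p", pp), paste0("e", i, ".tsv"))
    write.table(epochs$data[i, , , drop = TRUE],
                file.path(dir, files[i]), sep = "\t",
                row.names = FALSE, col.names = FALSE)
  }
  manifest <- cbind(epochs$meta, file = files)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param dir container directory.
#' @return an `epoch_set`.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  manifest <- read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  design <- design_spec(meta$study_label, meta$modality, meta$participants,
                        checks = as.list(meta$checks),
                        trials_per_cell = unlist(meta$trials_per_cell),
                        sampling_rate = meta$sampling_rate,
                        epoch_window = meta$epoch_window,
                        channel_labels = meta$channel_labels)
  n <- nrow(manifest)
  n_ch <- length(meta$channel_labels)
  n_samp <- length(meta$time_ms)
  data <- array(0, dim = c(n, n_ch, n_samp),
                dimnames = list(NULL, meta$channel_labels, NULL))
  for (i in seq_len(n)) {
    m <- as.matrix(read.table(file.path(dir, manifest$file[i]), sep = "\t"))
    data[i, , ] <- m
  }
  new_epoch_set(design,
                data,
                manifest[, c("participant", "trial", "cell")],
                meta$time_ms)
}

#' Write an instance set (averaged epochs) to a directory container
#'
#' Same layout as [write_epochs()]; the manifest carries participant, class
#' label, T and the instance index.
#'
#' @param x an `instance_set`.
#' @param dir target directory.
#' @return `dir`, invisibly.
#' @export
write_instances <- function(x, dir) {
  stopifnot(inherits(x, "instance_set"))
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)
  meta <- list(check = x$check, levels = x$levels,
               n_averaged = x$n_averaged, modality = x$modality,
               channel_labels = x$channel_labels, time_ms = x$time_ms,
               fs = x$fs)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- character(nrow(x$meta))
  for (i in seq_len(nrow(x$meta))) {
    pp <- x$meta$participant[i]
    pdir <- file.path(dir, "data", paste0("p", pp))
    if (!dir.exists(pdir)) dir.create(pdir)
    files[i] <- file.path("data", paste0("p", pp), paste0("i", i, ".tsv"))
    write.table(x$data[i, , , drop = TRUE], file.path(dir, files[i]),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(participant = x$meta$participant,
                         class = x$meta$label, T = x$n_averaged,
                         index = seq_len(nrow(x$meta)), file = files)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read an instance set written by [write_instances()]
#' @param dir container directory.
#' @return an `instance_set`.
#' @export
read_instances <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  manifest <- read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  n <- nrow(manifest)
  data <- array(0, dim = c(n, length(meta$channel_labels),
                           length(meta$time_ms)),
                dimnames = list(NULL, meta$channel_labels, NULL))
  for (i in seq_len(n))
    data[i, , ] <- as.matrix(read.table(file.path(dir, manifest$file[i]),
                                        sep = "\t"))
  structure(list(data = data,
                 meta = data.frame(participant = manifest$participant,
                                   label = manifest$class,
                                   cell = NA_character_,
                                   stringsAsFactors = FALSE),
                 check = meta$check, levels = meta$levels,
                 n_averaged = meta$n_averaged, modality = meta$modality,
                 channel_labels = meta$channel_labels,
                 time_ms = meta$time_ms, fs = meta$fs),
            class = "instance_set")
}

#' Write a feature table as TSV
#'
#' Columns: participant, label, then one column per feature named
#' `channel|block|descriptor`.
#'
#' @param ft a `feature_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- cbind(ft$meta, as.data.frame(ft$X, check.names = FALSE))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an evaluation report to JSON
#' @param report an `eval_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a JSON run/generation configuration
#' @param path JSON file.
#' @return named list.
#' @export
read_config <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
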