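# Factorial cells -> check labels, within-participant trial averaging,
# channel-set restriction.

#' Relabel factorial trials by one appraisal check
#'
#' Projects each trial's condition cell onto the level of a single check
#' (e.g. a (novel, pleasant) oddball cell becomes simply "novel" for the
#' novelty task), so every trial contributes to every check's classifier.
#' All trials are retained; only the label changes.
#'
#' @param epochs an `epoch_set`.
#' @param check name of a check declared in the design.
#' @return object of class `instance_set` with `n_averaged = 1`; its meta
#'   keeps the original cell so cell-wise groupings remain possible.
#' @export
relabel <- function(epochs, check) {
  stopifnot(inherits(epochs, "epoch_set"))
  checks <- epochs$design$checks
  if (!check %in% names(checks))
    stop2("relabel: unknown check '", check, "'; available: ",
          paste(names(checks), collapse = ", "))
  pos <- match(check, names(checks))
  label <- vapply(strsplit(epochs$meta$cell, "/", fixed = TRUE),
                  `[[`, character(1), pos)
  meta <- data.frame(participant = epochs$meta$participant,
                     label = label, cell = epochs$meta$cell,
                     stringsAsFactors = FALSE)
  structure(list(data = epochs$data, meta = meta, check = check,
                 levels = checks[[check]], n_averaged = 1L,
                 modality = epochs$design$modality,
                 channel_labels = epochs$channel_labels,
                 time_ms = epochs$time_ms, fs = epochs$fs),
            class = "instance_set")
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf("instance_set: %d instances, check '%s' (%s), T = %s, %d channels\n",
              nrow(x$meta), x$check, paste(x$levels, collapse = "/"),
              as.character(x$n_averaged), length(x$channel_labels)))
  invisible(x)
}

#' Average groups of T same-class trials within participant
#'
#' For numeric T, consecutive (chronological) groups of T trials of the same
#' participant and group are replaced by their sample-wise mean; the
#' remainder `n mod T` trials are discarded. `T = "all"` yields one mean per
#' group, `T = 1` is the identity. Grouping is by class label by default;
#' `group_by = "cell"` reproduces condition-cell bookkeeping (25
#' participants x 6 cells -> 150 all-trial instances).
#'
#' @param x an `instance_set` (from [relabel()]).
#' @param T one of 1, 2, 3, 4, 5, 10, 20 or "all".
#' @param group_by "label" (default) or "cell".
#' @param shuffle if TRUE, trials are shuffled within each group (seeded)
#'   before grouping; default FALSE (chronological order).
#' @param seed seed for the optional shuffle.
#' @return a new `instance_set` with `n_averaged = T`.
#' @export
average_trials <- function(x, T, group_by = c("label", "cell"),
                           shuffle = FALSE, seed = 1L) {
  stopifnot(inherits(x, "instance_set"))
  group_by <- match.arg(group_by)
  all_T <- identical(T, "all")
  if (!all_T) {
    if (!T %in% c(1, 2, 3, 4, 5, 10, 20))
      stop2("average_trials: T must be one of 1,2,3,4,5,10,20 or \"all\"")
    T <- as.integer(T)
    if (T == 1L) { x$n_averaged <- 1L; return(x) }
  }
  key <- paste(x$meta$participant, x$meta[[group_by]], sep = "\r")
  groups <- split(seq_len(nrow(x$meta)), key)
  out_rows <- list()
  for (g in groups) {
    if (shuffle) g <- with_seed(derive_seed(seed, g[1]), sample(g))
    n <- length(g)
    if (all_T) {
      out_rows[[length(out_rows) + 1L]] <- list(idx = g)
    } else {
      k <- n %/% T
      if (k == 0L) {
        warning(sprintf("average_trials: group with %d trial(s) < T = %d yields no instances", n, T))
        next
      }
      for (j in seq_len(k))
        out_rows[[length(out_rows) + 1L]] <-
          list(idx = g[((j - 1L) * T + 1L):(j * T)])
    }
  }
  n_out <- length(out_rows)
  d <- dim(x$data)
  data <- array(0, dim = c(n_out, d[2], d[3]),
                dimnames = list(NULL, dimnames(x$data)[[2]], NULL))
  meta <- data.frame(participant = integer(n_out), label = character(n_out),
                     cell = character(n_out), stringsAsFactors = FALSE)
  for (i in seq_len(n_out)) {
    idx <- out_rows[[i]]$idx
    m <- x$data[idx, , , drop = FALSE]
    data[i, , ] <- if (length(idx) == 1L) m[1, , ] else colMeans(m, dims = 1)
    meta$participant[i] <- x$meta$participant[idx[1]]
    meta$label[i] <- x$meta$label[idx[1]]
    cells <- unique(x$meta$cell[idx])
    meta$cell[i] <- if (length(cells) == 1L) cells else NA_character_
  }
  x$data <- data
  x$meta <- meta
  x$n_averaged <- if (all_T) "all" else T
  x
}

# Channel sets used in the classification experiments (regions of interest
# from the source studies' conventional ERP analyses, plus their immediate
# neighbours, plus the full montage).
channel_sets <- list(
  "study1-set1" = c("Fz", "Cz", "Pz"),
  "study1-set2" = c("Fz", "Cz", "Pz", "FCz", "F1", "F2", "AFz", "C1", "C2",
                    "CPz", "P1", "P2", "POz"),
  "study2-set1" = c("Fz", "FCz", "Pz", "POz"),
  "study2-set2" = c("Fz", "FCz", "Pz", "POz", "F1", "F2", "AFz", "FC1",
                    "FC2", "Cz", "P1", "P2", "CPz", "PO3", "PO4", "Oz")
)

#' Resolve a named channel set
#'
#' @param set_name "study1-set1" (3 midline channels), "study1-set2" (those
#'   plus neighbours, 13), "study2-set1" (4), "study2-set2" (16), or
#'   "study1-set3"/"study2-set3"/"all64" (full 64-channel montage).
#' @return character vector of channel labels.
#' @export
resolve_channel_set <- function(set_name) {
  if (set_name %in% c("study1-set3", "study2-set3", "all64"))
    return(biosemi64_labels())
  if (!set_name %in% names(channel_sets))
    stop2("resolve_channel_set: unknown set '", set_name, "'; available: ",
          paste(c(names(channel_sets), "study1-set3", "study2-set3"),
                collapse = ", "))
  channel_sets[[set_name]]
}

#' Restrict an instance or epoch set to a channel subset
#'
#' @param x an `instance_set` or `epoch_set`.
#' @param channels either a set name understood by [resolve_channel_set()]
#'   or an explicit character vector of labels; the channel dimension is
#'   restricted and reordered to this list.
#' @return object of the same class with the reduced channel dimension.
#' @export
select_channels <- function(x, channels) {
  stopifnot(inherits(x, "instance_set") || inherits(x, "epoch_set"))
  if (length(channels) == 1L && !channels %in% x$channel_labels)
    channels <- resolve_channel_set(channels)
  missing <- setdiff(channels, x$channel_labels)
  if (length(missing))
    stop2("select_channels: label(s) not present: ",
          paste(missing, collapse = ", "))
  idx <- match(channels, x$channel_labels)
  x$data <- x$data[, idx, , drop = FALSE]
  x$channel_labels <- channels
  x
}
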