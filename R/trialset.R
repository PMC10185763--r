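# Trial containers, event lists and epoching.

#' Labeled multichannel trial container
#'
#' The universal input/output container of the pipeline: event-locked
#' epochs of a multichannel recording with one integer class label per
#' trial.
#'
#' @param data Numeric array, `trials x channels x samples`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param labels Integer class label per trial.
#' @param channel_names Optional character vector, one per channel.
#' @param meta Free-form provenance list.
#' @return An object of class `trial_set`.
#' @examples
#' ts <- trial_set(array(rnorm(10 * 2 * 100), c(10, 2, 100)), 100,
#'                 rep(0:1, 5))
#' ts
#' @export
trial_set <- function(data, fs, labels, channel_names = NULL, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-d array (trials x channels x samples)")
  d <- dim(data)
  if (d[3] < 2L) stop("need at least 2 samples per trial")
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) stop("fs must be > 0")
  labels <- as.integer(labels)
  if (length(labels) != d[1])
    stop("labels length (", length(labels), ") must equal trial count (",
         d[1], ")")
  if (anyNA(labels)) stop("labels must not contain NA")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[2]))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != d[2])
    stop("channel_names length must equal channel count")
  structure(list(data = data, fs = fs, labels = labels,
                 channel_names = channel_names, meta = meta),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set: %d trials x %d channels x %d samples @ %g Hz>\n",
              d[1], d[2], d[3], x$fs))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.trial_set <- function(object, ...) {
  d <- dim(object$data)
  structure(list(trials = d[1], channels = d[2], samples = d[3],
                 fs = object$fs, duration_s = d[3] / object$fs,
                 labels = table(object$labels),
                 channel_names = object$channel_names),
            class = "summary.trial_set")
}

#' @export
print.summary.trial_set <- function(x, ...) {
  cat(sprintf("trial_set: %d trials, %d channels, %d samples (%.3g s @ %g Hz)\n",
              x$trials, x$channels, x$samples, x$duration_s, x$fs))
  print(x$labels)
  invisible(x)
}

#' Subset trials of a trial_set
#'
#' @param x A [trial_set()].
#' @param i Trial indices (any form accepted by array indexing).
#' @param ... Ignored.
#' @return A `trial_set` with the selected trials.
#' @export
`[.trial_set` <- function(x, i, ...) {
  trial_set(x$data[i, , , drop = FALSE], x$fs, x$labels[i],
            x$channel_names, x$meta)
}

#' Number of trials
#' @param ts A [trial_set()].
#' @return Integer trial count.
#' @export
n_trials <- function(ts) dim(ts$data)[1]

#' Write / read a trial container
#'
#' Trial sets are stored as single-file R serializations (RDS) holding the
#' `data`, `fs`, `labels`, `channel_names` and `meta` fields; the
#' write-then-read round trip is bit-exact on every field. Reading
#' validates the container and names any missing required field.
#'
#' @param ts A [trial_set()].
#' @param path File path (conventionally `.rds`).
#' @return `write_trialset` returns `path` invisibly; `read_trialset`
#'   returns a `trial_set`.
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  saveRDS(unclass(ts), path)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj)) stop("not a trial container: ", path)
  for (field in c("data", "fs", "labels")) {
    if (is.null(obj[[field]]))
      stop("trial container is missing required field: ", field)
  }
  trial_set(obj$data, obj$fs, obj$labels, obj$channel_names,
            if (is.null(obj$meta)) list() else obj$meta)
}

#' Event list for a continuous recording
#'
#' @param onsets 0-based sample indices into the recording, strictly
#'   increasing and non-negative.
#' @param labels Integer label per event.
#' @return An object of class `event_list`.
#' @export
event_list <- function(onsets, labels) {
  onsets <- as.integer(round(onsets))
  labels <- as.integer(labels)
  if (length(onsets) != length(labels))
    stop("onsets and labels must have equal length")
  if (length(onsets) && (any(onsets < 0L) || any(diff(onsets) <= 0L)))
    stop("onsets must be non-negative and strictly increasing")
  structure(list(onsets = onsets, labels = labels), class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list: %d events, %d label value(s)>\n",
              length(x$onsets), length(unique(x$labels))))
  invisible(x)
}

#' Continuous multichannel recording
#'
#' @param data Numeric matrix, `channels x samples`.
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional character vector.
#' @param events Optional [event_list()] (e.g. parsed annotations).
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, fs, channel_names = NULL,
                                 events = NULL) {
  if (!is.matrix(data)) stop("data must be a channels x samples matrix")
  if (fs <= 0) stop("fs must be > 0")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must equal channel count")
  if (!is.null(events)) stopifnot(inherits(events, "event_list"))
  structure(list(data = data, fs = fs,
                 channel_names = as.character(channel_names),
                 events = events),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording: %d channels x %d samples @ %g Hz%s>\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (!is.null(x$events))
                sprintf(", %d events", length(x$events$onsets)) else ""))
  invisible(x)
}

#' Epoch a continuous recording into event-locked trials
#'
#' Cuts one trial per event using a half-open window in samples:
#' `[onset + round(start_s * fs), onset + round(start_s * fs) + L)` with
#' `L = round((end_s - start_s) * fs)` and 0-based onsets. Events whose
#' full window does not lie inside the recording are dropped with a
#' warning; the number of returned trials plus the number of dropped
#' events always equals the event count.
#'
#' @param recording A [continuous_recording()].
#' @param events An [event_list()].
#' @param window Numeric `c(start_s, end_s)` relative to each onset,
#'   `end_s > start_s`.
#' @return A [trial_set()]; `meta$window` and `meta$n_dropped` record the
#'   epoching provenance.
#' @export
epoch_continuous <- function(recording, events, window) {
  stopifnot(inherits(recording, "continuous_recording"),
            inherits(events, "event_list"))
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be c(start_s, end_s) with end_s > start_s")
  fs <- recording$fs
  nsamp <- ncol(recording$data)
  L <- as.integer(round((window[2] - window[1]) * fs))
  if (L < 2L) stop("window too short: ", L, " samples")
  i0 <- events$onsets + as.integer(round(window[1] * fs))   # 0-based
  keep <- i0 >= 0L & (i0 + L) <= nsamp
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    warning(n_drop, " event(s) dropped: window outside the recording")
  if (!any(keep)) stop("no events survive epoching")
  i0 <- i0[keep]
  nch <- nrow(recording$data)
  out <- array(NA_real_, c(length(i0), nch, L))
  for (j in seq_along(i0))
    out[j, , ] <- recording$data[, (i0[j] + 1L):(i0[j] + L), drop = FALSE]
  trial_set(out, fs, events$labels[keep], recording$channel_names,
            meta = list(window = window, n_dropped = n_drop))
}

#' Read an events table
#'
#' Tab-separated file with columns `onset_sample` (0-based) and `label`.
#'
#' @param path File path.
#' @return An [event_list()].
#' @export
read_events_tsv <- function(path) {
  tab <- utils::read.delim(path)
  for (col in c("onset_sample", "label"))
    if (is.null(tab[[col]])) stop("events file is missing column: ", col)
  event_list(tab$onset_sample, tab$label)
}
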