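# ERPAC-driven frequency band selection (ERPAC-FBS) and the mixed
# filter-bank synthesis.
#
# Per slow rhythm: coupling matrices are computed per channel, averaged,
# compressed over time into a frequency profile, smoothed with a
# Savitzky-Golay filter; the top peaks become intervals [p - BW, p + BW]
# whose bandpass outputs are superimposed into one mixed signal per rhythm.

#' Compress an ERPAC matrix over time
#'
#' Reduces the time x frequency coupling matrix to a frequency profile by
#' taking, per frequency bin, the maximum (default) or mean coupling over
#' non-missing time points. Frequency columns that are missing at every
#' time point are dropped with a warning.
#'
#' @param matrix An [erpac_matrix()].
#' @param mode `"max"` (default) or `"mean"`.
#' @return An object of class `frequency_profile`: `freqs`, `intensity`,
#'   `compression`.
#' @export
compress_time <- function(matrix, mode = c("max", "mean")) {
  stopifnot(inherits(matrix, "erpac_matrix"))
  mode <- match.arg(mode)
  V <- matrix$values
  if (!length(V)) stop("empty ERPAC matrix")
  all_missing <- colSums(!is.na(V)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " frequency column(s) dropped: all missing")
    V <- V[, !all_missing, drop = FALSE]
    freqs <- matrix$freqs[!all_missing]
  } else freqs <- matrix$freqs
  if (!ncol(V)) stop("empty ERPAC matrix after dropping missing columns")
  intensity <- if (mode == "max") apply(V, 2L, max, na.rm = TRUE)
               else colMeans(V, na.rm = TRUE)
  structure(list(freqs = freqs, intensity = as.numeric(intensity),
                 compression = mode),
            class = "frequency_profile")
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat(sprintf("<frequency_profile (%s): %d bins, %g-%g Hz, peak %.3f @ %g Hz>\n",
              x$compression, length(x$freqs), min(x$freqs), max(x$freqs),
              max(x$intensity), x$freqs[which.max(x$intensity)]))
  invisible(x)
}

#' Smoothed peak detection on a frequency profile
#'
#' Applies Savitzky-Golay smoothing, then locates strict interior local
#' maxima (a sign change of the first difference). Peak intensities are
#' read from the smoothed profile. Peaks are returned sorted by descending
#' intensity, ties broken toward the lower frequency. A profile with no
#' interior maximum (e.g. strictly monotone) yields zero rows; downstream
#' selection then falls back to the full analysis range.
#'
#' @param profile A [compress_time()] result.
#' @param window Odd smoothing window length in grid bins (default 11).
#' @param polyorder Savitzky-Golay polynomial order (default 3).
#' @return A data frame with columns `peak_hz`, `intensity`.
#' @export
find_peaks_smoothed <- function(profile, window = 11L, polyorder = 3L) {
  stopifnot(inherits(profile, "frequency_profile"))
  n <- length(profile$intensity)
  if (window %% 2L != 1L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > n) stop("profile shorter than the smoothing window")
  sm <- signal::sgolayfilt(profile$intensity, p = polyorder, n = window)
  idx <- which(diff(sign(diff(sm))) < 0) + 1L
  idx <- idx[sm[idx] > sm[idx - 1L] & sm[idx] > sm[idx + 1L]]  # strict maxima
  # discard maxima indistinguishable from zero (float wiggle in flat tails)
  idx <- idx[sm[idx] > 1e-6 * max(abs(sm))]
  peaks <- data.frame(peak_hz = profile$freqs[idx], intensity = sm[idx])
  peaks[order(-peaks$intensity, peaks$peak_hz), , drop = FALSE]
}

#' Select the top coupling peaks as sub-band intervals
#'
#' The `n_peaks` strongest peaks become intervals `[p - bw, p + bw]`
#' clipped to the analysis range. Fewer peaks than requested yield fewer
#' intervals; zero peaks yield a single fallback interval covering the
#' full range, with `fallback_used = TRUE`.
#'
#' @param peaks Data frame from [find_peaks_smoothed()].
#' @param n_peaks Number of intervals to keep (default 2).
#' @param bw Interval half width in Hz (default 10).
#' @param range Analysis range `c(lo, hi)` in Hz for clipping and fallback.
#' @return A list with `intervals` (data frame `peak_hz`, `intensity`,
#'   `lo`, `hi`, ordered by descending intensity) and `fallback_used`.
#' @export
select_top_bands <- function(peaks, n_peaks = 2L, bw = 10, range = c(70, 200)) {
  if (bw <= 0) stop("bw must be > 0")
  stopifnot(length(range) == 2L, range[2] > range[1])
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(list(intervals = data.frame(peak_hz = mean(range),
                                       intensity = NA_real_,
                                       lo = range[1], hi = range[2]),
                fallback_used = TRUE))
  }
  top <- utils::head(peaks, n_peaks)
  list(intervals = data.frame(peak_hz = top$peak_hz,
                              intensity = top$intensity,
                              lo = pmax(top$peak_hz - bw, range[1]),
                              hi = pmin(top$peak_hz + bw, range[2])),
       fallback_used = FALSE)
}

#' Fit the ERPAC frequency-band selector
#'
#' The full selection procedure: for each slow rhythm (delta, theta,
#' alpha, beta by default), coupling matrices are computed per channel
#' ([erpac_matrix()]), averaged across channels ([aggregate_erpac()]),
#' compressed over time ([compress_time()]); smoothed peaks are located
#' ([find_peaks_smoothed()]) and the strongest become sub-band intervals
#' ([select_top_bands()]). Selection pools all supplied trials; to select
#' on a label subset, subset the trial set first (e.g. `trials[labels ==
#' 1]`).
#'
#' @param trials A [trial_set()] with at least 3 trials.
#' @param config A [default_config()]-style configuration.
#' @param channels Channel indices to aggregate over (default: all).
#' @return An object of class `erpac_fbs` carrying, per rhythm, the
#'   selected intervals with peak frequencies and intensities, the
#'   aggregated coupling matrices and frequency profiles, advisory
#'   bandwidth-constraint flags, and the configuration fingerprint.
#'   Methods: [print()], [summary()], [coef()], [plot()];
#'   feed it to [build_mixed_signals()] to synthesize the filter bank.
#' @export
erpac_fbs <- function(trials, config = default_config(), channels = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  config <- validate_config(config)
  d <- dim(trials$data)
  if (d[1] < 3L) stop("insufficient trials: ERPAC-FBS needs at least 3")
  if (stats::var(as.numeric(trials$data)) == 0)
    stop("degenerate input: trial data are constant")
  if (is.null(channels)) channels <- seq_len(d[2])
  fs <- trials$fs
  e <- config$erpac
  grid <- amplitude_grid(e$grid_lo, e$grid_hi, e$grid_step, e$grid_halfwidth)
  .check_grid_nyquist(grid, fs)
  time_step <- max(1L, as.integer(round(e$time_step_s * fs)))
  time_idx <- seq(1L, d[3], by = time_step)
  low_bands <- canonical_low_bands(config$bands$include_gamma)
  order <- config$filter$order

  per_channel <- vector("list", length(channels))
  for (ci in seq_along(channels)) {
    X <- t(trials$data[, channels[ci], ])
    per_channel[[ci]] <- .erpac_channel(X, fs, low_bands, grid, time_idx,
                                        order, config$filter$pad)
  }
  times <- (time_idx - 1L) / fs

  sel <- config$selection
  selection <- list(); profiles <- list(); matrices <- list()
  advisories <- list()
  for (b in seq_along(low_bands)) {
    band <- low_bands[[b]]
    mats <- lapply(seq_along(channels), function(ci)
      .new_erpac_matrix(per_channel[[ci]][[band$name]], times, grid$centers,
                        band, d[1], channels[ci]))
    agg <- aggregate_erpac(mats)
    prof <- compress_time(agg, sel$compression)
    peaks <- find_peaks_smoothed(prof, sel$sg_window, sel$sg_polyorder)
    chosen <- select_top_bands(peaks, sel$n_peaks, sel$bw, grid$range)
    selection[[band$name]] <- c(list(band = band), chosen)
    profiles[[band$name]] <- prof
    matrices[[band$name]] <- agg
    advisories[[band$name]] <- check_bandwidth_constraint(band, 2 * sel$bw)
  }

  structure(list(selection = selection, profiles = profiles,
                 matrices = matrices, grid = grid, advisories = advisories,
                 n_trials = d[1], channels = channels, fs = fs,
                 config = config, config_hash = .config_hash(config),
                 call = match.call()),
            class = "erpac_fbs")
}

#' @export
print.erpac_fbs <- function(x, ...) {
  cat(sprintf("ERPAC frequency-band selection (%d trials, %d channel(s))\n",
              x$n_trials, length(x$channels)))
  for (nm in names(x$selection)) {
    s <- x$selection[[nm]]
    iv <- s$intervals
    desc <- paste(sprintf("[%g, %g] Hz (peak %g Hz, %.3f)",
                          iv$lo, iv$hi, iv$peak_hz, iv$intensity),
                  collapse = ", ")
    cat(sprintf("  %-6s -> %s%s\n", nm, desc,
                if (s$fallback_used) "  [fallback: full range]" else ""))
  }
  invisible(x)
}

#' @export
coef.erpac_fbs <- function(object, ...) {
  do.call(rbind, lapply(names(object$selection), function(nm) {
    iv <- object$selection[[nm]]$intervals
    cbind(data.frame(low_band = nm), iv,
          fallback = object$selection[[nm]]$fallback_used)
  }))
}

#' @export
summary.erpac_fbs <- function(object, ...) {
  out <- list(coef = coef.erpac_fbs(object),
              advisories = object$advisories,
              n_trials = object$n_trials,
              channels = object$channels,
              config_hash = object$config_hash)
  class(out) <- "summary.erpac_fbs"
  out
}

#' @export
print.summary.erpac_fbs <- function(x, ...) {
  cat("Selected high-gamma sub-bands per rhythm:\n")
  print(x$coef, row.names = FALSE)
  viol <- Filter(function(a) !a$ok, x$advisories)
  if (length(viol))
    cat("Sideband-resolution advisories (bandwidth < 2 x upper phase freq):",
        paste(vapply(viol, `[[`, "", "band"), collapse = ", "), "\n")
  cat(sprintf("%d trials over channel(s) %s; config hash %d\n", x$n_trials,
              paste(x$channels, collapse = ","), x$config_hash))
  invisible(x)
}

#' Plot ERPAC-FBS frequency profiles with selected intervals
#'
#' One panel per rhythm: the compressed coupling profile over the
#' amplitude grid, with the selected sub-band intervals shaded.
#'
#' @param x An [erpac_fbs()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.erpac_fbs <- function(x, ...) {
  nb <- length(x$profiles)
  old <- graphics::par(mfrow = c(nb, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (nm in names(x$profiles)) {
    p <- x$profiles[[nm]]
    graphics::plot(p$freqs, p$intensity, type = "l",
                   xlab = "amplitude frequency (Hz)", ylab = "coupling",
                   main = nm, ...)
    iv <- x$selection[[nm]]$intervals
    for (r in seq_len(nrow(iv)))
      graphics::rect(iv$lo[r], graphics::par("usr")[3], iv$hi[r],
                     graphics::par("usr")[4],
                     col = grDevices::adjustcolor("steelblue", 0.25),
                     border = NA)
  }
  invisible(x)
}

#' Synthesize the mixed filter-bank signals
#'
#' Per rhythm, bandpasses every trial/channel into each selected sub-band
#' and superimposes (sums) the results into one mixed signal; overlapping
#' intervals are double-counted unless `merge_overlaps` was set in the
#' configuration. With `include_low = TRUE` the rhythm's own
#' low-frequency bandpass output is added to its mixed signal.
#'
#' @param trials A [trial_set()].
#' @param selection An [erpac_fbs()] fit (or one restored via
#'   [read_selection_json()]).
#' @param include_low Override of the configured low-frequency inclusion
#'   flag (default: the value in `selection$config`).
#' @return An object of class `filter_bank_output`: `data` is a
#'   `trials x bands x channels x samples` array; plus `fs`, `labels`,
#'   `bands`, `include_low`.
#' @export
build_mixed_signals <- function(trials, selection, include_low = NULL) {
  stopifnot(inherits(trials, "trial_set"), inherits(selection, "erpac_fbs"))
  if (is.null(include_low)) include_low <- selection$config$bands$include_low
  d <- dim(trials$data)
  fs <- trials$fs
  order <- selection$config$filter$order
  pad <- selection$config$filter$pad
  band_names <- names(selection$selection)
  out <- array(0, c(d[1], length(band_names), d[2], d[3]))
  # samples x (channels * trials) view, channel fastest
  X <- matrix(aperm(trials$data, c(3L, 2L, 1L)), nrow = d[3])
  for (b in seq_along(band_names)) {
    s <- selection$selection[[band_names[b]]]
    iv <- s$intervals
    if (isTRUE(selection$config$selection$merge_overlaps))
      iv <- .merge_intervals(iv)
    acc <- matrix(0, d[3], ncol(X))
    for (r in seq_len(nrow(iv))) {
      sub <- band_spec(sprintf("%s_sub%d", band_names[b], r),
                       iv$lo[r], iv$hi[r])
      .check_band_nyquist(sub, fs)
      acc <- acc + bandpass(X, fs, sub, order, pad)
    }
    if (isTRUE(include_low))
      acc <- acc + bandpass(X, fs, s$band, order, pad)
    out[, b, , ] <- aperm(array(acc, c(d[3], d[2], d[1])), c(3L, 2L, 1L))
  }
  structure(list(data = out, fs = fs, labels = trials$labels,
                 bands = band_names, include_low = isTRUE(include_low)),
            class = "filter_bank_output")
}

.merge_intervals <- function(iv) {
  iv <- iv[order(iv$lo), , drop = FALSE]
  keep <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) for (r in 2:nrow(iv)) {
    last <- nrow(keep)
    if (iv$lo[r] <= keep$hi[last]) keep$hi[last] <- max(keep$hi[last], iv$hi[r])
    else keep <- rbind(keep, iv[r, ])
  }
  keep
}

#' @export
print.filter_bank_output <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<filter_bank_output: %d trials x %d bands x %d channels x %d samples @ %g Hz%s>\n",
    d[1], d[2], d[3], d[4], x$fs,
    if (x$include_low) ", low-frequency signal included" else ""))
  invisible(x)
}

#' Serialize / restore a band selection as JSON
#'
#' Stores per rhythm the selected intervals, peak frequencies, intensities
#' and fallback flags, together with the filter order, analysis range and
#' low-frequency inclusion flag, so that a selection fitted on one data
#' set can be applied to another (e.g. from the command line).
#'
#' @param selection An [erpac_fbs()] fit.
#' @param path Output path.
#' @return `write_selection_json` returns `path` invisibly;
#'   `read_selection_json` returns a reduced `erpac_fbs` object sufficient
#'   for [build_mixed_signals()].
#' @export
write_selection_json <- function(selection, path) {
  stopifnot(inherits(selection, "erpac_fbs"))
  payload <- list(
    bands = lapply(selection$selection, function(s) list(
      low_band = list(name = s$band$name, lo = s$band$lo, hi = s$band$hi),
      intervals = s$intervals,
      fallback_used = s$fallback_used)),
    grid_range = selection$grid$range,
    filter_order = selection$config$filter$order,
    filter_pad = selection$config$filter$pad,
    include_low = selection$config$bands$include_low,
    merge_overlaps = selection$config$selection$merge_overlaps,
    bw = selection$config$selection$bw,
    n_trials = selection$n_trials,
    config_hash = selection$config_hash)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_selection_json
#' @export
read_selection_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sel <- lapply(p$bands, function(s) list(
    band = band_spec(s$low_band$name, s$low_band$lo, s$low_band$hi),
    intervals = as.data.frame(s$intervals),
    fallback_used = isTRUE(s$fallback_used)))
  cfg <- default_config()
  cfg$filter$order <- as.integer(p$filter_order)
  if (!is.null(p$filter_pad)) cfg$filter$pad <- p$filter_pad
  cfg$bands$include_low <- isTRUE(p$include_low)
  cfg$selection$merge_overlaps <- isTRUE(p$merge_overlaps)
  cfg$selection$bw <- p$bw
  structure(list(selection = sel,
                 grid = amplitude_grid(p$grid_range[1], p$grid_range[2]),
                 n_trials = p$n_trials, config = validate_config(cfg),
                 config_hash = p$config_hash),
            class = "erpac_fbs")
}
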