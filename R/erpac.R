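# Event-related phase-amplitude coupling (ERPAC).
#
# At each retained time point, the coupling between the phase of a slow
# rhythm and the amplitude of a high-gamma bin is measured ACROSS TRIALS
# with the circular-linear correlation: with r_sx = cor(sin(phi), a),
# r_cx = cor(cos(phi), a) and r_sc = cor(sin(phi), cos(phi)),
#
#   p_cl = sqrt((r_sx^2 + r_cx^2 - 2 r_sx r_cx r_sc) / (1 - r_sc^2)).
#
# Scanning the amplitude over a grid of narrow high-gamma bins gives a
# time x frequency coupling matrix per channel and phase band.

#' Circular-linear correlation between phase and amplitude
#'
#' The coupling statistic `p_cl` in `[0, 1]` between a circular variable
#' (phase, radians) and a linear one (amplitude), built from the Pearson
#' correlations of the amplitude with the sine and cosine of the phase
#' (see the package vignette). The value is invariant under phase rotation
#' and under positive affine maps of the amplitude.
#'
#' @param phases Phase angles in radians, one per observation (trial).
#' @param amplitudes Amplitudes, same length, with nonzero variance.
#' @return `p_cl` in `[0, 1]` (clipped against floating-point overshoot).
#' @examples
#' circular_linear_correlation(c(0, pi / 2, pi, 3 * pi / 2), c(0, 1, 0, -1))
#' @export
circular_linear_correlation <- function(phases, amplitudes) {
  n <- length(phases)
  if (length(amplitudes) != n) stop("phases and amplitudes length mismatch")
  if (n < 3L) stop("need at least 3 paired observations")
  s <- sin(phases); co <- cos(phases)
  if (stats::sd(amplitudes) == 0) stop("zero-variance amplitude")
  if (stats::sd(s) == 0) stop("zero-variance sin(phase)")
  if (stats::sd(co) == 0) stop("zero-variance cos(phase)")
  r_sx <- stats::cor(s, amplitudes)
  r_cx <- stats::cor(co, amplitudes)
  r_sc <- stats::cor(s, co)
  if (abs(r_sc) >= 1 - 1e-12)
    stop("degenerate phase distribution: |cor(sin, cos)| = 1")
  num <- r_sx^2 + r_cx^2 - 2 * r_sx * r_cx * r_sc
  p <- sqrt(max(0, num) / (1 - r_sc^2))
  min(max(p, 0), 1)
}

# Vectorized p_cl over matched columns of PH and AM (rows = trials,
# columns = time points). Degenerate columns yield NA.
.cl_corr_cols <- function(PH, AM) {
  n <- nrow(PH)
  S <- sin(PH); C <- cos(PH)
  m_s <- colMeans(S); m_c <- colMeans(C); m_a <- colMeans(AM)
  v_s <- colMeans(S * S) - m_s^2
  v_c <- colMeans(C * C) - m_c^2
  v_a <- colMeans(AM * AM) - m_a^2
  c_sa <- colMeans(S * AM) - m_s * m_a
  c_ca <- colMeans(C * AM) - m_c * m_a
  c_sc <- colMeans(S * C) - m_s * m_c
  eps <- 1e-14
  ok <- v_s > eps & v_c > eps & v_a > eps
  r_sx <- c_sa / sqrt(v_s * v_a)
  r_cx <- c_ca / sqrt(v_c * v_a)
  r_sc <- c_sc / sqrt(v_s * v_c)
  ok <- ok & abs(r_sc) < 1 - 1e-12
  num <- r_sx^2 + r_cx^2 - 2 * r_sx * r_cx * r_sc
  p <- sqrt(pmax(num, 0) / (1 - r_sc^2))
  p <- pmin(pmax(p, 0), 1)
  p[!ok] <- NA_real_
  p
}

#' Amplitude scan grid over the high-gamma range
#'
#' Narrow bins whose envelope is correlated with low-frequency phase. The
#' default covers 70-200 Hz with centers every 2 Hz from 80 to 190 and a
#' half bandwidth of 10 Hz. The bin bandwidth (2 x halfwidth) must be at
#' least twice the modulating frequency, or the modulation sidebands at
#' `carrier +/- f_mod` fall outside the bin at the true carrier and the
#' coupling profile develops a false null exactly there; 10 Hz resolves
#' modulators up to the alpha band while keeping each bin's bandpass
#' stable.
#'
#' @param lo,hi Scan range in Hz.
#' @param step Center spacing in Hz.
#' @param halfwidth Half bandwidth of each bin in Hz.
#' @return An object of class `amplitude_grid` with `centers`, `halfwidth`
#'   and `range`.
#' @export
amplitude_grid <- function(lo = 70, hi = 200, step = 2, halfwidth = 10) {
  stopifnot(lo > 0, hi > lo, step > 0, halfwidth > 0)
  centers <- seq(lo + halfwidth, hi - halfwidth, by = step)
  if (!length(centers)) stop("empty amplitude grid")
  structure(list(centers = centers, halfwidth = halfwidth,
                 range = c(lo, hi)),
            class = "amplitude_grid")
}

#' @export
print.amplitude_grid <- function(x, ...) {
  cat(sprintf("<amplitude_grid: %d bins of +/-%g Hz, centers %g-%g Hz>\n",
              length(x$centers), x$halfwidth, min(x$centers), max(x$centers)))
  invisible(x)
}

# Per-channel coupling engine. X: samples x trials matrix of one channel.
# Returns one times x freqs matrix per phase band, sharing one padding
# pass and the amplitude envelopes (which do not depend on the phase band)
# across all bands: pad once, then per band filter -> analytic signal ->
# crop at the retained time points.
.erpac_channel <- function(X, fs, phase_bands, grid, time_idx, order = 4L,
                           pad = "lp") {
  n <- nrow(X)
  npad <- .pad_length(n, fs)
  Xp <- .pad_signal(X, npad, pad)
  rows <- npad + time_idx
  analytic_at <- function(band) {
    Z <- .analytic_fft(cpp_sosfiltfilt(.butter_sos(fs, band, order), Xp))
    t(Z[rows, , drop = FALSE])                               # trials x times
  }
  amp_t <- lapply(seq_along(grid$centers), function(j)
    Mod(analytic_at(band_spec(sprintf("hg_%g", grid$centers[j]),
                              grid$centers[j] - grid$halfwidth,
                              grid$centers[j] + grid$halfwidth))))
  out <- vector("list", length(phase_bands))
  names(out) <- vapply(phase_bands, `[[`, "", "name")
  for (i in seq_along(phase_bands)) {
    PH <- Arg(analytic_at(phase_bands[[i]]))
    vals <- matrix(NA_real_, length(time_idx), length(grid$centers))
    for (j in seq_along(grid$centers))
      vals[, j] <- .cl_corr_cols(PH, amp_t[[j]])
    out[[i]] <- vals
  }
  out
}

.check_grid_nyquist <- function(grid, fs) {
  if (max(grid$centers) + grid$halfwidth >= fs / 2)
    stop("amplitude grid exceeds the Nyquist frequency (fs = ", fs, " Hz)")
}

#' Event-related PAC matrix for one channel and phase band
#'
#' Computes, for every retained time point (every `time_step` samples) and
#' every amplitude-grid bin, the circular-linear correlation across trials
#' between the instantaneous phase of `phase_band` and the instantaneous
#' amplitude of the bin. One bandpass + Hilbert pass per band per trial is
#' reused across time points. Time points where a statistic is degenerate
#' (zero variance) are recorded as missing, not zero.
#'
#' @param trials A [trial_set()] with at least 3 trials.
#' @param channel Channel index.
#' @param phase_band A [band_spec()] for the slow rhythm.
#' @param grid An [amplitude_grid()]; must lie below Nyquist.
#' @param time_step Time decimation in samples (default 10 ms).
#' @param order Butterworth order.
#' @param pad Edge-padding mode, as in [bandpass()].
#' @return An object of class `erpac_matrix`: `values` (times x
#'   frequencies, in `[0, 1]` or `NA`), `times` (seconds relative to epoch
#'   start), `freqs` (bin centers, Hz), `phase_band`, `n_trials`,
#'   `channels`.
#' @export
erpac_matrix <- function(trials, channel, phase_band, grid = amplitude_grid(),
                         time_step = NULL, order = 4L,
                         pad = c("lp", "reflect")) {
  pad <- match.arg(pad)
  stopifnot(inherits(trials, "trial_set"), inherits(phase_band, "band_spec"),
            inherits(grid, "amplitude_grid"))
  d <- dim(trials$data)
  if (d[1] < 3L) stop("insufficient trials: ERPAC needs at least 3")
  if (channel < 1L || channel > d[2]) stop("invalid channel index")
  .check_grid_nyquist(grid, trials$fs)
  if (is.null(time_step)) time_step <- max(1L, round(0.010 * trials$fs))
  time_idx <- seq(1L, d[3], by = as.integer(time_step))
  X <- t(trials$data[, channel, ])                 # samples x trials
  vals <- .erpac_channel(X, trials$fs, list(phase_band), grid, time_idx,
                         order, pad)[[1]]
  .new_erpac_matrix(vals, (time_idx - 1L) / trials$fs, grid$centers,
                    phase_band, d[1], channel)
}

.new_erpac_matrix <- function(values, times, freqs, phase_band, n_trials,
                              channels) {
  structure(list(values = values, times = times, freqs = freqs,
                 phase_band = phase_band, n_trials = n_trials,
                 channels = channels),
            class = "erpac_matrix")
}

#' @export
print.erpac_matrix <- function(x, ...) {
  cat(sprintf(
    "<erpac_matrix: %d times x %d freqs, phase %s, %d trials, channel(s) %s>\n",
    nrow(x$values), ncol(x$values), format(x$phase_band), x$n_trials,
    paste(x$channels, collapse = ",")))
  invisible(x)
}

#' Comodulogram-style image of an ERPAC matrix
#'
#' @param x An [erpac_matrix()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.erpac_matrix <- function(x, ...) {
  graphics::image(x$times, x$freqs, x$values,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "time (s)", ylab = "amplitude frequency (Hz)",
                  main = sprintf("ERPAC, phase %s", format(x$phase_band)), ...)
  invisible(x)
}

#' Aggregate ERPAC matrices across channels
#'
#' Elementwise mean over channels, ignoring missing cells (a cell missing
#' in every channel stays missing). All inputs must share identical time
#' and frequency axes, phase band and trial count.
#'
#' @param matrices A list of [erpac_matrix()] objects.
#' @return An [erpac_matrix()] whose `channels` lists all contributors.
#' @export
aggregate_erpac <- function(matrices) {
  if (inherits(matrices, "erpac_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, TRUE, "erpac_matrix")))
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!isTRUE(all.equal(m$times, ref$times)) ||
        !isTRUE(all.equal(m$freqs, ref$freqs)) ||
        !identical(m$phase_band$name, ref$phase_band$name) ||
        m$n_trials != ref$n_trials)
      stop("axis mismatch across ERPAC matrices")
  }
  if (length(matrices) == 1L) return(ref)
  arr <- vapply(matrices, function(m) m$values,
                matrix(0, nrow(ref$values), ncol(ref$values)))
  sums <- rowSums(ifelse(is.na(arr), 0, arr), dims = 2L)
  cnts <- rowSums(!is.na(arr), dims = 2L)
  mean_vals <- ifelse(cnts > 0L, sums / cnts, NA_real_)
  .new_erpac_matrix(mean_vals, ref$times, ref$freqs, ref$phase_band,
                    ref$n_trials,
                    unlist(lapply(matrices, `[[`, "channels")))
}
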