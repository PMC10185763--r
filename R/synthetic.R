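# Synthetic event-locked trials with controlled phase-amplitude coupling.
#
# Each coupled channel carries
#   x(t) = A_m sin(2 pi f_mod t + psi)
#        + g A_c [1 + m cos(2 pi f_mod t + psi + phi0)] sin(2 pi f_car t + psi')
#        + noise,
# with the slow-rhythm phase psi and the carrier phase psi' drawn fresh per
# trial, so the coupling is invisible in any single trial and only emerges
# across trials (exactly what the event-related coupling statistic
# measures). Uncoupled channels carry the unmodulated rhythm plus noise.
# The class gain g scales the carrier, emulating the task-locked
# high-gamma power increase that distinguishes movement from rest.

#' Specification of a synthetic coupled data set
#'
#' Defaults mirror the recording regime the pipeline targets: 1000 Hz
#' sampling, 2 s event-locked trials, 8 channels of which 2 carry the
#' coupled carrier, a 10 Hz (alpha) modulating rhythm, a 110 Hz high-gamma
#' carrier at coupling depth 0.8, and a pink + white noise floor
#' calibrated to 0 dB in-band (70-200 Hz) signal-to-noise for a unit
#' carrier. The default class design has a "rest" class 0 (no modulation,
#' attenuated carrier) and an "active" class 1 (full carrier, depth 0.8).
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Trial length, s.
#' @param n_trials Trials per class.
#' @param n_channels Total channels.
#' @param f_mod Modulating rhythm frequency, Hz; must fall inside one of
#'   the canonical low bands.
#' @param f_car High-gamma carrier frequency, Hz; must fall inside the
#'   70-200 Hz analysis range and below Nyquist.
#' @param depth Coupling depth `m` in `[0, 1]` of the active class.
#' @param coupling_phase Phase offset `phi0` (radians) between the rhythm
#'   and the envelope maximum.
#' @param a_mod,a_car Rhythm and carrier amplitudes.
#' @param snr_db In-band (70-200 Hz) signal-to-noise ratio in dB for a
#'   unit-gain carrier; sets the noise scale.
#' @param pink_fraction Fraction of noise power with a 1/f spectrum (the
#'   rest is white).
#' @param coupled_channels Indices of channels carrying the carrier.
#' @param class_design Named list mapping class label to
#'   `list(f_car, depth, gain)`; `NULL` gives the two-class default
#'   (`0`: depth 0, gain 0.25; `1`: `depth`, gain 1).
#' @param seed Random seed used by [generate_labeled_dataset()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(fs = 1000, duration_s = 2, n_trials = 30,
                           n_channels = 8, f_mod = 10, f_car = 110,
                           depth = 0.8, coupling_phase = 0,
                           a_mod = 1, a_car = 1, snr_db = 0,
                           pink_fraction = 0.8,
                           coupled_channels = c(1L, 2L),
                           class_design = NULL, seed = 1L) {
  if (is.null(class_design))
    class_design <- list(`0` = list(f_car = f_car, depth = 0, gain = 0.25),
                         `1` = list(f_car = f_car, depth = depth, gain = 1))
  low <- canonical_low_bands(FALSE)
  in_low <- any(vapply(low, function(b) f_mod >= b$lo && f_mod <= b$hi, TRUE))
  if (!in_low) stop("f_mod must lie inside a canonical low band")
  for (cls in class_design) {
    if (cls$f_car >= fs / 2) stop("carrier at or above Nyquist")
    if (cls$f_car < 70 || cls$f_car > 200)
      stop("carrier must lie in the 70-200 Hz analysis range")
    if (cls$depth < 0 || cls$depth > 1) stop("depth must be in [0, 1]")
  }
  if (max(coupled_channels) > n_channels || min(coupled_channels) < 1)
    stop("coupled_channels out of range")
  noise <- .calibrate_noise(fs, duration_s, a_car, snr_db, pink_fraction)
  structure(list(fs = fs, duration_s = duration_s, n_trials = n_trials,
                 n_channels = n_channels, f_mod = f_mod, f_car = f_car,
                 depth = depth, coupling_phase = coupling_phase,
                 a_mod = a_mod, a_car = a_car, snr_db = snr_db,
                 pink_fraction = pink_fraction,
                 sigma_pink = noise$sigma_pink, sigma_white = noise$sigma_white,
                 coupled_channels = as.integer(coupled_channels),
                 class_design = class_design, seed = seed),
            class = "synthetic_spec")
}

# Noise scale such that the 70-200 Hz noise power equals the carrier power
# a_car^2 / 2 divided by 10^(snr_db / 10). Band shares follow the flat
# (white) and 1/f (pink) spectral shapes; the pink spectrum is cut at the
# trial's fundamental frequency.
.calibrate_noise <- function(fs, duration_s, a_car, snr_db, pink_fraction) {
  lo <- 70; hi <- min(200, 0.999 * fs / 2)
  f0 <- 1 / duration_s
  white_share <- (hi - lo) / (fs / 2 - f0)
  pink_share <- log(hi / lo) / log((fs / 2) / f0)
  target_band_power <- (a_car^2 / 2) / 10^(snr_db / 10)
  denom <- pink_fraction * pink_share + (1 - pink_fraction) * white_share
  total <- target_band_power / denom
  list(sigma_pink = sqrt(pink_fraction * total),
       sigma_white = sqrt((1 - pink_fraction) * total))
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec: %d ch x %.3g s @ %g Hz, f_mod %g Hz, %d class(es) x %d trials>\n",
    x$n_channels, x$duration_s, x$fs, x$f_mod, length(x$class_design),
    x$n_trials))
  for (nm in names(x$class_design)) {
    cls <- x$class_design[[nm]]
    cat(sprintf("  class %s: carrier %g Hz, depth %g, gain %g\n",
                nm, cls$f_car, cls$depth, cls$gain))
  }
  invisible(x)
}

#' 1/f (pink) noise
#'
#' Zero-mean unit-variance noise whose power spectral density falls off as
#' 1/f, generated by shaping a white spectrum with `1/sqrt(f)` amplitude
#' and inverting the FFT.
#'
#' @param n Number of samples (`0` yields an empty vector).
#' @param fs Sampling rate, Hz (bookkeeping; the slope is scale-free).
#' @param seed Optional seed; when given the output is reproducible.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, seed = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0L) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  if (n == 1L) return(0)
  nf <- n %/% 2L
  f <- seq_len(nf) * fs / n
  amp <- 1 / sqrt(f)
  re <- stats::rnorm(nf); im <- stats::rnorm(nf)
  spec <- complex(real = amp * re, imaginary = amp * im)
  full <- complex(length.out = n)
  full[2:(nf + 1L)] <- spec
  if (n %% 2L == 0L) {
    full[nf + 1L] <- complex(real = amp[nf] * re[nf], imaginary = 0)
    if (nf > 1L) full[n:(nf + 2L)] <- Conj(spec[1:(nf - 1L)])
  } else {
    full[n:(nf + 2L)] <- Conj(spec[1:nf])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate one phase-amplitude-coupled trial
#'
#' Draws the rhythm and carrier phases from the current RNG stream (so a
#' data-set-level seed governs reproducibility) and returns one trial.
#' Coupled channels carry the rhythm plus the phase-modulated carrier;
#' uncoupled channels carry the unmodulated rhythm; all channels receive
#' independent pink + white noise.
#'
#' @param spec A [synthetic_spec()].
#' @param class_id Class label; must name an entry of `spec$class_design`.
#' @return A `channels x samples` matrix.
#' @export
generate_pac_trial <- function(spec, class_id) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cls <- spec$class_design[[as.character(class_id)]]
  if (is.null(cls)) stop("class ", class_id, " not in the class design")
  if (cls$f_car >= spec$fs / 2) stop("carrier at or above Nyquist")
  n <- round(spec$fs * spec$duration_s)
  t <- (seq_len(n) - 1L) / spec$fs
  psi <- stats::runif(1, 0, 2 * pi)
  psi2 <- stats::runif(1, 0, 2 * pi)
  rhythm <- spec$a_mod * sin(2 * pi * spec$f_mod * t + psi)
  env <- 1 + cls$depth * cos(2 * pi * spec$f_mod * t + psi + spec$coupling_phase)
  carrier <- cls$gain * spec$a_car * env * sin(2 * pi * cls$f_car * t + psi2)
  out <- matrix(0, spec$n_channels, n)
  for (ch in seq_len(spec$n_channels)) {
    noise <- spec$sigma_pink * pink_noise(n, spec$fs) +
      spec$sigma_white * stats::rnorm(n)
    out[ch, ] <- rhythm + noise +
      if (ch %in% spec$coupled_channels) carrier else 0
  }
  out
}

#' Generate a labeled synthetic data set
#'
#' Balanced classes (`spec$n_trials` per class), shuffled trial order,
#' deterministic under `spec$seed`; the full specification is recorded in
#' the result's `meta`.
#'
#' @param spec A [synthetic_spec()] with at least 2 classes (use a
#'   one-class design explicitly when only coupled trials are needed).
#' @return A [trial_set()].
#' @export
generate_labeled_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!length(spec$class_design)) stop("class design is empty")
  set.seed(spec$seed)
  class_ids <- names(spec$class_design)
  n_total <- spec$n_trials * length(class_ids)
  n <- round(spec$fs * spec$duration_s)
  data <- array(0, c(n_total, spec$n_channels, n))
  labels <- integer(n_total)
  i <- 0L
  for (cid in class_ids) for (k in seq_len(spec$n_trials)) {
    i <- i + 1L
    data[i, , ] <- generate_pac_trial(spec, cid)
    labels[i] <- as.integer(cid)
  }
  ord <- sample.int(n_total)
  trial_set(data[ord, , , drop = FALSE], spec$fs, labels[ord],
            meta = list(synthetic_spec = unclass(spec)))
}

#' Generate a continuous recording with embedded events
#'
#' Concatenates synthetic trials separated by noise-only gaps into one
#' continuous recording, returning the recording together with the event
#' list of trial onsets — the natural fixture for [epoch_continuous()].
#'
#' @param spec A [synthetic_spec()].
#' @param gap_s Inter-trial gap, s.
#' @return A [continuous_recording()] whose `$events` mark trial onsets.
#' @export
generate_continuous <- function(spec, gap_s = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- round(spec$fs * spec$duration_s)
  ngap <- round(spec$fs * gap_s)
  class_ids <- rep(names(spec$class_design), each = spec$n_trials)
  class_ids <- sample(class_ids)
  n_ev <- length(class_ids)
  total <- ngap + n_ev * (n + ngap)
  data <- matrix(0, spec$n_channels, total)
  for (ch in seq_len(spec$n_channels))
    data[ch, ] <- spec$sigma_pink * pink_noise(total, spec$fs) +
      spec$sigma_white * stats::rnorm(total)
  onsets <- integer(n_ev)
  pos <- ngap
  for (j in seq_len(n_ev)) {
    tr <- generate_pac_trial(spec, class_ids[j])
    data[, (pos + 1L):(pos + n)] <- data[, (pos + 1L):(pos + n)] + tr
    onsets[j] <- pos                      # 0-based
    pos <- pos + n + ngap
  }
  continuous_recording(data, spec$fs,
                       events = event_list(onsets, as.integer(class_ids)))
}
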