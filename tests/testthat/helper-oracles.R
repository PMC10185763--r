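# Shared test oracles and fixture builders. Everything is generated in
# code; no stored data.

# FFT band-power oracle: total power of x attributable to [lo, hi) Hz.
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1L) * fs / n
  p <- Mod(stats::fft(x))^2 / n
  sum(p[(f >= lo & f < hi) | (f > fs - hi & f <= fs - lo)])
}

# Unwrap phase angles (radians) into a continuous trajectory.
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# Direct-formula circular-linear correlation: three Pearson correlations
# composed explicitly, independent of the package's vectorized path.
pcl_oracle <- function(phi, a) {
  pearson <- function(x, y) {
    mean((x - mean(x)) * (y - mean(y))) / (stats::sd(x) * stats::sd(y)) *
      length(x) / (length(x) - 1)
  }
  r_sx <- pearson(sin(phi), a)
  r_cx <- pearson(cos(phi), a)
  r_sc <- pearson(sin(phi), cos(phi))
  sqrt((r_sx^2 + r_cx^2 - 2 * r_sx * r_cx * r_sc) / (1 - r_sc^2))
}

# Small coupled trial set for ERPAC/selection tests: one class, carrier at
# f_car modulated by an alpha rhythm.
coupled_trials <- function(n_trials = 60, fs = 500, duration_s = 1,
                           n_channels = 2, depth = 0.8, f_car = 110,
                           seed = 1, snr_db = 0) {
  spec <- synthetic_spec(fs = fs, duration_s = duration_s,
                         n_trials = n_trials, n_channels = n_channels,
                         coupled_channels = seq_len(min(2, n_channels)),
                         snr_db = snr_db, seed = seed,
                         class_design = list(`1` = list(f_car = f_car,
                                                        depth = depth,
                                                        gain = 1)))
  generate_labeled_dataset(spec)
}

# Two-class set whose discriminative signal lives in the carrier band
# (rest: attenuated unmodulated carrier; active: full coupled carrier).
two_class_trials <- function(n_trials = 40, fs = 500, duration_s = 1,
                             n_channels = 4, seed = 1) {
  spec <- synthetic_spec(fs = fs, duration_s = duration_s,
                         n_trials = n_trials, n_channels = n_channels,
                         coupled_channels = 1:2, seed = seed)
  generate_labeled_dataset(spec)
}

# Compact decoder configuration sized for tests.
test_decoder_config <- function() {
  cfg <- default_config()
  cfg$decoder$f1 <- 4L
  cfg$decoder$f2 <- 8L
  cfg$decoder$kernel <- 64L
  cfg$decoder$epochs <- 25L
  cfg$decoder$patience <- 8L
  cfg$decoder$dropout <- 0.25
  cfg
}

# erpac_matrix on a synthetic erpac_matrix-shaped object, for reduction
# oracles.
fake_erpac <- function(values, freqs = NULL, times = NULL) {
  if (is.null(freqs)) freqs <- seq_len(ncol(values)) * 2 + 78
  if (is.null(times)) times <- seq_len(nrow(values)) * 0.01
  pacband:::.new_erpac_matrix(values, times, freqs,
                              band_spec("alpha", 8, 12), 10L, 1L)
}
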