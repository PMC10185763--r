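test_that("time compression reduces to columnwise max or mean", {
  cmat <- matrix(0.4, 6, 5)
  expect_equal(compress_time(fake_erpac(cmat), "max")$intensity, rep(0.4, 5))
  expect_equal(compress_time(fake_erpac(cmat), "mean")$intensity, rep(0.4, 5))

  spike <- matrix(0, 6, 5); spike[3, 2] <- 1
  expect_equal(compress_time(fake_erpac(spike), "max")$intensity,
               c(0, 1, 0, 0, 0))

  set.seed(40)
  v <- matrix(runif(60), 10)
  v[sample(60, 6)] <- NA
  fm <- fake_erpac(v)
  expect_equal(compress_time(fm, "max")$intensity,
               apply(v, 2, max, na.rm = TRUE))
  expect_equal(compress_time(fm, "mean")$intensity, colMeans(v, na.rm = TRUE))
  # default mode is max
  expect_equal(compress_time(fm)$compression, "max")
})

test_that("all-missing frequency columns are dropped with a warning", {
  v <- matrix(runif(30), 6)
  v[, 2] <- NA
  expect_warning(p <- compress_time(fake_erpac(v)), "dropped")
  expect_length(p$intensity, 4L)
})

test_that("smoothed peak finding locates and orders maxima", {
  freqs <- seq(80, 190, by = 2)
  # unimodal noiseless bump at 120 Hz
  prof <- structure(list(freqs = freqs,
                         intensity = exp(-(freqs - 120)^2 / 200),
                         compression = "max"),
                    class = "frequency_profile")
  pk <- find_peaks_smoothed(prof)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$peak_hz - 120), 2.1)

  # strictly monotone profile: no interior peak, selection falls back
  mono <- structure(list(freqs = freqs,
                         intensity = seq(0.1, 0.9, length.out = length(freqs)),
                         compression = "max"),
                    class = "frequency_profile")
  pk2 <- find_peaks_smoothed(mono)
  expect_equal(nrow(pk2), 0L)
  sel <- select_top_bands(pk2, range = c(70, 200))
  expect_true(sel$fallback_used)
  expect_equal(c(sel$intervals$lo, sel$intervals$hi), c(70, 200))

  # two bumps, 0.9 @ 120 and 0.7 @ 180: ordered by descending intensity
  prof2 <- structure(list(freqs = freqs,
                          intensity = 0.9 * exp(-(freqs - 120)^2 / 100) +
                            0.7 * exp(-(freqs - 180)^2 / 100),
                          compression = "max"),
                     class = "frequency_profile")
  pk3 <- find_peaks_smoothed(prof2)
  expect_gte(nrow(pk3), 2L)
  expect_lt(abs(pk3$peak_hz[1] - 120), 2.1)
  expect_lt(abs(pk3$peak_hz[2] - 180), 2.1)
  expect_gt(pk3$intensity[1], pk3$intensity[2])

  expect_error(find_peaks_smoothed(prof, window = 10), "odd")
  expect_error(
    find_peaks_smoothed(structure(list(freqs = 1:5, intensity = runif(5),
                                       compression = "max"),
                                  class = "frequency_profile")),
    "shorter than the smoothing window")
})

test_that("top-band selection builds [p - bw, p + bw] intervals", {
  one <- data.frame(peak_hz = 110, intensity = 0.8)
  sel <- select_top_bands(one, n_peaks = 2, bw = 10, range = c(70, 200))
  expect_equal(c(sel$intervals$lo, sel$intervals$hi), c(100, 120))
  expect_false(sel$fallback_used)

  # hand-execution of the selection rule: peaks 80/120/180 with
  # intensities 0.5/0.9/0.7 -> [110,130], [170,190]
  pk <- data.frame(peak_hz = c(120, 180, 80), intensity = c(0.9, 0.7, 0.5))
  sel2 <- select_top_bands(pk, n_peaks = 2, bw = 10, range = c(70, 200))
  expect_equal(sel2$intervals$lo, c(110, 170))
  expect_equal(sel2$intervals$hi, c(130, 190))

  # clipping at the analysis range
  edge <- data.frame(peak_hz = 195, intensity = 0.9)
  sel3 <- select_top_bands(edge, bw = 10, range = c(70, 200))
  expect_equal(sel3$intervals$hi, 200)
  expect_error(select_top_bands(one, bw = 0), "bw must be")
})

test_that("the full selector recovers a known coupled carrier", {
  ts0 <- coupled_trials(n_trials = 50, fs = 500, n_channels = 2, seed = 41)
  sel <- erpac_fbs(ts0)
  expect_s3_class(sel, "erpac_fbs")
  expect_named(sel$selection, c("delta", "theta", "alpha", "beta"))
  for (s in sel$selection) expect_lte(nrow(s$intervals), 2L)
  top <- sel$selection$alpha$intervals[1, ]
  expect_true(top$lo <= 110 && 110 <= top$hi)
  cf <- coef(sel)
  expect_true(all(c("low_band", "peak_hz", "lo", "hi") %in% names(cf)))
})

test_that("the selector rejects degenerate input", {
  flat <- trial_set(array(1, c(5, 2, 400)), 500, rep(0:1, length.out = 5))
  expect_error(erpac_fbs(flat), "degenerate input")
  ts0 <- coupled_trials(n_trials = 5, fs = 500, seed = 42)
  expect_error(erpac_fbs(ts0[1:2]), "insufficient trials")
})

test_that("selection is deterministic for identical input and config", {
  ts0 <- coupled_trials(n_trials = 12, fs = 500, n_channels = 1, seed = 43)
  s1 <- erpac_fbs(ts0)
  s2 <- erpac_fbs(ts0)
  expect_identical(coef(s1), coef(s2))
  expect_identical(s1$profiles, s2$profiles)
})

test_that("mixed signals superimpose the selected bands", {
  fs <- 500
  set.seed(44)
  ts0 <- trial_set(array(rnorm(4 * 2 * 600), c(4, 2, 600)), fs, rep(0:1, 2))
  sel <- erpac_fbs(coupled_trials(n_trials = 10, fs = fs, seed = 45))
  # override with hand-made disjoint intervals for the power checks
  sel$selection <- lapply(sel$selection, function(s) {
    s$intervals <- data.frame(peak_hz = c(100, 160), intensity = c(1, 1),
                              lo = c(90, 150), hi = c(110, 170))
    s
  })
  fb <- build_mixed_signals(ts0, sel)
  expect_equal(dim(fb$data), c(4L, 4L, 2L, 600L))

  x <- ts0$data[1, 1, ]
  y <- fb$data[1, 1, 1, ]
  # disjoint-support additivity: mixed power ~ sum of the band powers
  p_mixed <- mean(y^2)
  p_parts <- mean(bandpass(x, fs, band_spec("a", 90, 110))^2) +
    mean(bandpass(x, fs, band_spec("b", 150, 170))^2)
  expect_lt(abs(p_mixed - p_parts) / p_parts, 0.05)
  # ... and the mixed signal is exactly the sum of the two bandpasses
  y2 <- bandpass(x, fs, band_spec("a", 90, 110)) +
    bandpass(x, fs, band_spec("b", 150, 170))
  expect_equal(y, y2, tolerance = 1e-10)
})

test_that("build_mixed_signals is linear in the input trials", {
  fs <- 500
  set.seed(46)
  mk <- function(arr) trial_set(arr, fs, c(0L, 1L))
  a1 <- array(rnorm(2 * 1 * 500), c(2, 1, 500))
  a2 <- array(rnorm(2 * 1 * 500), c(2, 1, 500))
  sel <- erpac_fbs(coupled_trials(n_trials = 10, fs = fs, seed = 47))
  sel$config$filter$pad <- "reflect"   # strictly linear padding
  f1 <- build_mixed_signals(mk(a1), sel)$data
  f2 <- build_mixed_signals(mk(a2), sel)$data
  f12 <- build_mixed_signals(mk(3 * a1 - 2 * a2), sel)$data
  expect_equal(f12, 3 * f1 - 2 * f2, tolerance = 1e-8)
})

test_that("include_low adds the rhythm's own band to its mixed signal", {
  fs <- 500
  t1 <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t1)                     # pure alpha tone
  ts0 <- trial_set(array(rep(x, each = 3), c(3, 1, fs)), fs, c(0L, 1L, 0L))
  sel <- erpac_fbs(coupled_trials(n_trials = 10, fs = fs, seed = 48))
  with_low <- build_mixed_signals(ts0, sel, include_low = TRUE)
  without <- build_mixed_signals(ts0, sel, include_low = FALSE)
  a_i <- which(with_low$bands == "alpha")
  rms <- function(v) sqrt(mean(v^2))
  expect_gt(rms(with_low$data[1, a_i, 1, ]) / rms(x), 0.5)
  expect_lt(rms(without$data[1, a_i, 1, ]) / rms(x), 0.01)
})

test_that("a full-range selection on band-limited input is a passband identity", {
  fs <- 1000
  set.seed(49)
  x <- bandpass(rnorm(2000), fs, band_spec("hg", 90, 180))
  ts0 <- trial_set(array(rep(x, each = 2), c(2, 1, 2000)), fs, 0:1)
  sel <- erpac_fbs(coupled_trials(n_trials = 10, fs = fs, duration_s = 2,
                                  seed = 50))
  sel$selection <- lapply(sel$selection, function(s) {
    s$intervals <- data.frame(peak_hz = 135, intensity = 1, lo = 70, hi = 200)
    s
  })
  fb <- build_mixed_signals(ts0, sel)
  y <- fb$data[1, 1, 1, ]
  idx <- 200:1800
  expect_lt(sqrt(mean((y[idx] - x[idx])^2)) / sqrt(mean(x[idx]^2)), 0.05)
})

test_that("selection JSON round trip preserves the intervals", {
  ts0 <- coupled_trials(n_trials = 10, fs = 500, seed = 51)
  sel <- erpac_fbs(ts0)
  path <- tempfile(fileext = ".json")
  write_selection_json(sel, path)
  back <- read_selection_json(path)
  expect_equal(coef(back)[c("low_band", "lo", "hi")],
               coef(sel)[c("low_band", "lo", "hi")])
  fb1 <- build_mixed_signals(ts0, sel)
  fb2 <- build_mixed_signals(ts0, back)
  expect_equal(fb1$data, fb2$data)
})
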