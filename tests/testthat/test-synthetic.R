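test_that("pink noise is reproducible, zero-mean, with ~1/f spectral slope", {
  expect_length(pink_noise(0, 1000), 0L)
  expect_identical(pink_noise(512, 1000, seed = 9), pink_noise(512, 1000, seed = 9))

  x <- pink_noise(2^16, 1000, seed = 10)
  expect_lt(abs(mean(x)), 1e-10)
  expect_equal(sd(x), 1, tolerance = 1e-6)
  # Welch-style PSD slope over 1-100 Hz by least squares in log-log
  sp <- stats::spec.pgram(stats::ts(x, frequency = 1000), spans = 31,
                          plot = FALSE, detrend = FALSE, taper = 0)
  keep <- sp$freq >= 1 & sp$freq <= 100
  slope <- coef(lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[[2]]
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})

test_that("generated trials express the designed coupling mechanics", {
  # no modulation, no noise: constant high-gamma envelope
  spec0 <- synthetic_spec(fs = 500, duration_s = 1, n_channels = 1,
                          coupled_channels = 1, snr_db = 120,
                          class_design = list(`1` = list(f_car = 110,
                                                         depth = 0, gain = 1)))
  set.seed(60)
  tr <- generate_pac_trial(spec0, 1)
  env <- hilbert_analytic(bandpass(tr[1, ], 500, high_gamma_band()),
                          500)$amplitude
  mid <- 100:400
  expect_lt(max(abs(env[mid] - mean(env[mid]))) / mean(env[mid]), 0.02)

  # carrier absent: essentially no high-gamma power
  spec1 <- synthetic_spec(fs = 500, duration_s = 1, n_channels = 1,
                          coupled_channels = 1, a_car = 1e-12, snr_db = 120,
                          class_design = list(`1` = list(f_car = 110,
                                                         depth = 0, gain = 0)))
  set.seed(61)
  tr1 <- generate_pac_trial(spec1, 1)
  expect_lt(band_power(tr1[1, ], 500, 70, 200) / band_power(tr1[1, ], 500, 0, 250),
            0.001)

  expect_error(generate_pac_trial(spec0, 99), "not in the class design")
})

test_that("strong coupling is detectable across trials where none exists at depth 0", {
  pcl_at_mid <- function(depth, seed) {
    ts0 <- coupled_trials(n_trials = 40, fs = 500, n_channels = 1,
                          depth = depth, seed = seed, snr_db = 30)
    fs <- 500
    ph <- am <- numeric(40)
    for (tr in 1:40) {
      x <- ts0$data[tr, 1, ]
      ph[tr] <- hilbert_analytic(bandpass(x, fs, band_spec("alpha", 8, 12)),
                                 fs)$phase[250]
      am[tr] <- hilbert_analytic(bandpass(x, fs, band_spec("c", 100, 120)),
                                 fs)$amplitude[250]
    }
    circular_linear_correlation(ph, am)
  }
  coupled <- pcl_at_mid(0.9, seed = 62)
  nulls <- vapply(1:20, function(s) pcl_at_mid(0, seed = 100 + s), 0)
  expect_gt(coupled, stats::quantile(nulls, 0.99))
})

test_that("labeled data sets are balanced, shuffled and reproducible", {
  spec <- synthetic_spec(fs = 500, duration_s = 1, n_trials = 30,
                         n_channels = 2, seed = 63)
  ts0 <- generate_labeled_dataset(spec)
  expect_equal(n_trials(ts0), 60L)
  expect_equal(as.numeric(table(ts0$labels)), c(30, 30))
  expect_identical(generate_labeled_dataset(spec)$data, ts0$data)
  # label order is shuffled, not blocked
  expect_false(all(ts0$labels == rep(0:1, each = 30)))
  expect_equal(ts0$meta$synthetic_spec$seed, 63)
})

test_that("trial spectra concentrate power at the rhythm and the carrier", {
  ts0 <- coupled_trials(n_trials = 10, fs = 500, n_channels = 1, seed = 64)
  x <- ts0$data[1, 1, ]
  total <- band_power(x, 500, 0, 250)
  share_mod <- band_power(x, 500, 8, 12) / total
  share_car <- band_power(x, 500, 100, 120) / total
  set.seed(65)
  nz <- pink_noise(500, 500)
  share_mod_null <- band_power(nz, 500, 8, 12) / band_power(nz, 500, 0, 250)
  share_car_null <- band_power(nz, 500, 100, 120) / band_power(nz, 500, 0, 250)
  expect_gt(share_mod, share_mod_null)
  expect_gt(share_car, share_car_null)
})

test_that("class information lives only in the designed carrier band", {
  ts0 <- two_class_trials(n_trials = 30, seed = 66)
  fs <- ts0$fs
  varfeat <- function(data) {
    # variance of the coupled channels' high-gamma signal, per trial
    vapply(seq_len(dim(data)[1]), function(i)
      stats::var(bandpass(data[i, 1, ], fs, high_gamma_band())), 0)
  }
  acc_of <- function(data) {
    f <- varfeat(data)
    thr <- stats::median(f)
    pred <- as.integer(f > thr)
    max(mean(pred == ts0$labels), mean((1L - pred) == ts0$labels))
  }
  expect_gt(acc_of(ts0$data), 0.9)
  # bandstop-remove the carrier band: accuracy collapses to chance
  stripped <- ts0$data
  for (i in seq_len(dim(stripped)[1])) for (ch in 1:2)
    stripped[i, ch, ] <- bandstop(ts0$data[i, ch, ], fs,
                                  band_spec("c", 100, 120))
  expect_lt(acc_of(stripped), 0.5 + 3 * sqrt(0.25 / n_trials(ts0)))
})

test_that("continuous mode embeds epochs recoverable by epoch_continuous", {
  spec <- synthetic_spec(fs = 250, duration_s = 1, n_trials = 4,
                         n_channels = 2, seed = 67)
  rec <- generate_continuous(spec, gap_s = 0.5)
  expect_s3_class(rec, "continuous_recording")
  expect_equal(length(rec$events$onsets), 8L)
  ts0 <- epoch_continuous(rec, rec$events, c(0, 1))
  expect_equal(n_trials(ts0), 8L)
  expect_equal(sort(unique(ts0$labels)), 0:1)
})
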