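test_that("p_cl is exactly 1 when amplitude is a linear function of sin(phase)", {
  expect_equal(circular_linear_correlation(c(0, pi / 2, pi, 3 * pi / 2),
                                           c(0, 1, 0, -1)), 1)
})

test_that("p_cl matches the direct-formula oracle on random instances", {
  set.seed(20)
  for (i in 1:25) {
    phi <- runif(50, 0, 2 * pi)
    a <- rnorm(50)
    expect_equal(circular_linear_correlation(phi, a), pcl_oracle(phi, a),
                 tolerance = 1e-13)
  }
})

test_that("p_cl declares its degenerate cases", {
  phi <- seq(0, 2 * pi, length.out = 21)[-21]
  expect_error(circular_linear_correlation(phi, rep(5, 20)),
               "zero-variance amplitude")
  expect_error(circular_linear_correlation(rep(1, 20), rnorm(20)),
               "zero-variance")
  expect_error(circular_linear_correlation(c(0, pi), c(1, 2)), "at least 3")
  # phases on a line through the circle: sin and cos perfectly correlated
  expect_error(circular_linear_correlation(c(0.3, 0.3 + pi, 0.3, 0.3 + pi),
                                           c(1, 2, 3, 4)), "degenerate|zero-variance")
})

test_that("p_cl is invariant to phase rotation and positive affine amplitude maps", {
  set.seed(21)
  for (i in 1:10) {
    phi <- runif(40, 0, 2 * pi)
    a <- rnorm(40)
    base <- circular_linear_correlation(phi, a)
    rot <- runif(1, -10, 10)
    expect_lt(abs(circular_linear_correlation((phi + rot) %% (2 * pi), a) -
                    base), 1e-9)
    s <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_lt(abs(circular_linear_correlation(phi, s * a + b) - base), 1e-12)
  }
})

test_that("null p_cl stays small at n = 200 (regression guard)", {
  set.seed(22)
  n <- 200; nsim <- 1000
  PH <- matrix(runif(n * nsim, 0, 2 * pi), n)
  AM <- matrix(rnorm(n * nsim), n)
  p <- pacband:::.cl_corr_cols(PH, AM)
  expect_lt(stats::quantile(p, 0.95), 0.25)
})

test_that("erpac_matrix honours its contract on coupled data", {
  ts0 <- coupled_trials(n_trials = 40, fs = 500, seed = 31)
  m <- erpac_matrix(ts0, 1, band_spec("alpha", 8, 12))
  expect_s3_class(m, "erpac_matrix")
  expect_equal(nrow(m$values), ceiling(dim(ts0$data)[3] / 5))  # 10 ms @ 500 Hz
  expect_equal(ncol(m$values), length(amplitude_grid()$centers))
  v <- m$values[!is.na(m$values)]
  expect_true(all(v >= 0 & v <= 1))
  # the frequency of maximal coupling (time-max profile) is near the carrier
  prof <- apply(m$values, 2, max, na.rm = TRUE)
  peak <- m$freqs[which.max(prof)]
  expect_lt(abs(peak - 110), amplitude_grid()$halfwidth + 2)
})

test_that("erpac_matrix equals the scalar statistic at a fixed cell", {
  ts0 <- coupled_trials(n_trials = 20, fs = 500, duration_s = 1, seed = 32,
                        n_channels = 1)
  grid <- amplitude_grid()
  m <- erpac_matrix(ts0, 1, band_spec("alpha", 8, 12), grid)
  fs <- ts0$fs
  # recompute two cells via the public single-signal composition
  j <- which(grid$centers == 110); ti <- 41L   # 0.4 s (time index 41 @ 10 ms)
  hi_band <- band_spec("x", grid$centers[j] - grid$halfwidth,
                       grid$centers[j] + grid$halfwidth)
  phases <- amps <- numeric(n_trials(ts0))
  for (tr in seq_len(n_trials(ts0))) {
    x <- ts0$data[tr, 1, ]
    phases[tr] <- hilbert_analytic(bandpass(x, fs, band_spec("alpha", 8, 12)),
                                   fs)$phase[(ti - 1) * 5 + 1]
    amps[tr] <- hilbert_analytic(bandpass(x, fs, hi_band),
                                 fs)$amplitude[(ti - 1) * 5 + 1]
  }
  expect_equal(m$values[ti, j], circular_linear_correlation(phases, amps),
               tolerance = 1e-3)
})

test_that("erpac_matrix rejects too few trials and out-of-range grids", {
  ts0 <- coupled_trials(n_trials = 20, fs = 500, seed = 33)
  expect_error(erpac_matrix(ts0[1:2], 1, band_spec("alpha", 8, 12)),
               "insufficient trials")
  expect_error(erpac_matrix(ts0, 99, band_spec("alpha", 8, 12)),
               "invalid channel")
  expect_error(erpac_matrix(coupled_trials(n_trials = 5, fs = 300, seed = 1,
                                           f_car = 100),
                            1, band_spec("alpha", 8, 12)),
               "Nyquist")
})

test_that("aggregation is the elementwise mean with identity on one channel", {
  set.seed(23)
  v1 <- matrix(runif(40), 8); v2 <- matrix(runif(40), 8)
  m1 <- fake_erpac(v1); m2 <- fake_erpac(v2)
  expect_identical(aggregate_erpac(list(m1))$values, v1)
  expect_equal(aggregate_erpac(list(m1, m1))$values, v1)
  agg <- aggregate_erpac(list(m1, m2))
  expect_equal(agg$values, (v1 + v2) / 2)
  expect_equal(agg$channels, c(1L, 1L))
  # missing cells are excluded from the mean, not zeroed
  v1[2, 3] <- NA
  agg2 <- aggregate_erpac(list(fake_erpac(v1), m2))
  expect_equal(agg2$values[2, 3], v2[2, 3])
  # axis mismatch
  m3 <- fake_erpac(matrix(runif(40), 8), freqs = seq(90, 98, 2))
  expect_error(aggregate_erpac(list(m1, m3)), "axis mismatch")
})
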