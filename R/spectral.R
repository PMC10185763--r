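# Zero-phase Butterworth filtering and Hilbert analytic signals.
#
# All operations accept either a numeric vector or a matrix with one signal
# per column (samples in rows), and return an object of the same shape.
# Signals are padded by min(1 s, length/4) at each end before filtering or
# the Hilbert transform and cropped afterwards, so that edge transients
# fall outside the returned samples.

.as_signal_matrix <- function(x) {
  if (is.matrix(x)) list(x = x, vec = FALSE)
  else list(x = matrix(as.numeric(x), ncol = 1L), vec = TRUE)
}

.pad_length <- function(n, fs) max(1L, min(as.integer(round(fs)), n %/% 4L))

# Linear-predictive padding: each column is extended at both ends by a
# Yule-Walker AR extrapolation fitted to the column itself. Oscillatory
# content is continued in phase across the boundary (a plain mirror puts a
# derivative kink at the data edge whose ringing bleeds well into
# narrowband filter output), and Yule-Walker estimates are always
# stationary, so the extension decays toward the mean instead of blowing
# up on noise.
.ar_order <- 24L

# mode "lp": linear-predictive extension (default; best edge accuracy, but
# the fitted coefficients depend on the data, so filtering is linear only
# away from the edges). mode "reflect": plain mirror (strictly linear).
.pad_signal <- function(X, npad, mode = c("lp", "reflect")) {
  mode <- match.arg(mode)
  if (mode == "lp") .lp_pad(X, npad) else .mirror_pad(X, npad)
}

.mirror_pad <- function(X, npad) {
  n <- nrow(X)
  if (npad >= n) stop("padding length must be smaller than the signal")
  if (npad == 0L) return(X)
  rbind(X[(npad + 1L):2L, , drop = FALSE], X,
        X[(n - 1L):(n - npad), , drop = FALSE])
}

.lp_pad <- function(X, npad) {
  n <- nrow(X)
  if (npad >= n) stop("padding length must be smaller than the signal")
  if (npad == 0L) return(X)
  p <- min(.ar_order, n %/% 3L)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  # autocovariances r_0..r_p, all columns at once
  r <- matrix(0, p + 1L, ncol(X))
  for (k in 0:p)
    r[k + 1L, ] <- colSums(Xc[seq_len(n - k), , drop = FALSE] *
                           Xc[(k + 1L):n, , drop = FALSE]) / n
  coefs <- matrix(0, p, ncol(X))
  for (j in seq_len(ncol(X))) {
    if (r[1L, j] <= 0) next                  # constant column: pad with mean
    R <- stats::toeplitz(r[seq_len(p), j])
    co <- tryCatch(solve(R, r[2:(p + 1L), j]), error = function(e) NULL)
    if (!is.null(co) && all(is.finite(co))) coefs[, j] <- co
  }
  fwd <- .ar_extend(Xc[(n - p + 1L):n, , drop = FALSE], coefs, npad)
  bwd <- .ar_extend(Xc[p:1L, , drop = FALSE], coefs, npad)
  out <- rbind(bwd[npad:1L, , drop = FALSE], Xc, fwd)
  sweep(out, 2L, mu, "+")
}

# window: the last p (centred) samples, oldest first; returns npad
# predicted rows.
.ar_extend <- function(window, coefs, npad) {
  p <- nrow(coefs); m <- ncol(coefs)
  hist <- rbind(window, matrix(0, npad, m))
  for (k in seq_len(npad)) {
    # rows (p+k-1):k are x[t-1], x[t-2], ..., x[t-p]; coefs row i is a_i
    hist[p + k, ] <- colSums(coefs * hist[(p + k - 1L):k, , drop = FALSE])
  }
  hist[(p + 1L):(p + npad), , drop = FALSE]
}

# Butterworth bandpass/bandstop design in zero-pole-gain form, returned as
# second-order sections (nsec x 6 matrix: b0 b1 b2 a0 a1 a2). The expanded
# transfer-function polynomial (as returned by tf-form designs) is
# numerically unstable for narrow low-frequency bands — an order-4 delta
# (1-3 Hz) bandpass at fs = 1000 Hz explodes in direct form — so the
# analog prototype is transformed and discretised pole by pole and
# realised as a biquad cascade.
.butter_sos <- function(fs, band, order, type = "pass") {
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * band$lo / fs)    # bilinear prewarp
  w2 <- fs2 * tan(pi * band$hi / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  theta <- pi * (2 * seq_len(order) - 1) / (2 * order)
  p_proto <- complex(real = -sin(theta), imaginary = cos(theta))
  if (type == "pass") {
    t1 <- p_proto * bw / 2
    disc <- sqrt(t1^2 - w0^2)
    poles_a <- c(t1 + disc, t1 - disc)
    zeros_a <- rep(0 + 0i, order)         # -> digital zeros at z = +1
    k_a <- bw^order
  } else {
    t1 <- (bw / 2) / p_proto
    disc <- sqrt(t1^2 - w0^2)
    poles_a <- c(t1 + disc, t1 - disc)
    zeros_a <- rep(c(1i * w0, -1i * w0), order)
    k_a <- 1
  }
  poles_d <- (fs2 + poles_a) / (fs2 - poles_a)
  zeros_d <- (fs2 + zeros_a) / (fs2 - zeros_a)
  k_d <- k_a * Re(prod(fs2 - zeros_a) / prod(fs2 - poles_a))
  # remaining zeros (from s = infinity) sit at z = -1; interleave them with
  # the z = +1 zeros so each bandpass section carries one of each
  n_extra <- length(poles_d) - length(zeros_d)
  if (n_extra > 0)
    zeros_d <- as.vector(rbind(zeros_d[seq_len(n_extra)],
                               rep(-1 + 0i, n_extra)))
  .zpk_to_sos(zeros_d, poles_d, k_d)
}

.conj_pairs <- function(v, tol = 1e-8) {
  used <- rep(FALSE, length(v))
  scale <- max(1, Mod(v))
  pairs <- list()
  for (i in seq_along(v)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(v[i])) > tol * scale) {
      cand <- which(!used & abs(Im(v) + Im(v[i])) < tol * scale * 10)
      j <- cand[which.min(Mod(v[cand] - Conj(v[i])))]
    } else {
      cand <- which(!used & abs(Im(v)) <= tol * scale)
      j <- cand[1]
    }
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(v[i], v[j])
  }
  pairs
}

.zpk_to_sos <- function(zeros, poles, gain) {
  zp <- .conj_pairs(zeros)
  pp <- .conj_pairs(poles)
  nsec <- length(pp)
  g <- abs(gain)^(1 / nsec)
  sos <- matrix(0, nsec, 6L)
  for (s in seq_len(nsec)) {
    z <- zp[[s]]; p <- pp[[s]]
    sos[s, 1:3] <- g * Re(c(1, -(z[1] + z[2]), z[1] * z[2]))
    sos[s, 4:6] <- Re(c(1, -(p[1] + p[2]), p[1] * p[2]))
  }
  if (gain < 0) sos[1, 1:3] <- -sos[1, 1:3]
  sos
}

.check_band_nyquist <- function(band, fs) {
  if (band$hi >= fs / 2)
    stop("band ", format(band), " is at or above the Nyquist frequency (fs = ",
         fs, " Hz)")
}

.min_signal_length <- function(order) 9L * (2L * order + 1L)

#' Zero-phase Butterworth bandpass filter
#'
#' Applies an order-`order` Butterworth bandpass forward and backward
#' (zero net phase shift, effective order `2 * order`) after reflect
#' padding. Output length equals input length.
#'
#' @param x Numeric vector, or matrix with one signal per column.
#' @param fs Sampling rate in Hz.
#' @param band A [band_spec()]; must lie below the Nyquist frequency.
#' @param order Butterworth order (default 4).
#' @param pad Edge-padding mode: `"lp"` (linear-predictive extension, the
#'   default; most accurate near the edges) or `"reflect"` (plain mirror;
#'   makes the operation strictly linear in `x`).
#' @return Filtered signal, same shape as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 500)
#' y <- bandpass(cos(2 * pi * 10 * t), 500, band_spec("alpha", 8, 12))
#' @export
bandpass <- function(x, fs, band, order = 4L, pad = c("lp", "reflect")) {
  .filter_signal(x, fs, band, order, type = "pass", pad = match.arg(pad))
}

#' Zero-phase Butterworth bandstop filter
#'
#' Complement of [bandpass()]: removes `band` from the signal. Mainly used
#' to verify that class information in synthetic data is confined to a
#' designed carrier band.
#'
#' @inheritParams bandpass
#' @return Filtered signal, same shape as `x`.
#' @export
bandstop <- function(x, fs, band, order = 4L, pad = c("lp", "reflect")) {
  .filter_signal(x, fs, band, order, type = "stop", pad = match.arg(pad))
}

.filter_signal <- function(x, fs, band, order, type, pad = "lp") {
  stopifnot(inherits(band, "band_spec"), fs > 0)
  .check_band_nyquist(band, fs)
  sm <- .as_signal_matrix(x)
  n <- nrow(sm$x)
  if (n <= .min_signal_length(order))
    stop("signal too short (", n, " samples) for stable order-", order,
         " filtering")
  sos <- .butter_sos(fs, band, order, type)
  npad <- .pad_length(n, fs)
  Y <- cpp_sosfiltfilt(sos, .pad_signal(sm$x, npad, pad))
  Y <- Y[(npad + 1L):(npad + n), , drop = FALSE]
  if (sm$vec) drop(Y) else Y
}

.analytic_fft <- function(X) {
  n <- nrow(X)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1L] <- 1
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2)] <- 2
  }
  Z <- stats::mvfft(X)
  Z <- Z * h
  stats::mvfft(Z, inverse = TRUE) / n
}

#' Hilbert analytic signal: instantaneous phase and amplitude
#'
#' Forms the analytic signal `z = x + i * H(x)` via the frequency-domain
#' construction (after reflect padding) and returns its modulus
#' (instantaneous amplitude envelope) and argument (instantaneous phase in
#' `(-pi, pi]`, zero at the maximum of a cosine). The caller is expected
#' to bandpass the signal first; alternatively set `apply_filter = TRUE`
#' to filter into `band` internally.
#'
#' @param x Numeric vector, or matrix with one signal per column.
#' @param fs Sampling rate in Hz.
#' @param band Optional [band_spec()] recorded with the result (and used to
#'   filter when `apply_filter = TRUE`).
#' @param apply_filter Bandpass `x` into `band` before the transform?
#' @param order Butterworth order used when `apply_filter = TRUE`.
#' @param pad Edge-padding mode, as in [bandpass()].
#' @return An object of class `analytic_signal`: a list with `phase`,
#'   `amplitude` (same shape as `x`), `band` and `fs`. An all-zero input
#'   is flagged with a warning (the phase is meaningless there).
#' @examples
#' t <- seq(0, 2, by = 1 / 500)
#' a <- hilbert_analytic(cos(2 * pi * 10 * t), 500)
#' range(a$amplitude[200:800])
#' @export
hilbert_analytic <- function(x, fs, band = NULL, apply_filter = FALSE,
                             order = 4L, pad = c("lp", "reflect")) {
  pad <- match.arg(pad)
  stopifnot(fs > 0)
  if (apply_filter) {
    if (is.null(band)) stop("apply_filter = TRUE requires a band")
    x <- bandpass(x, fs, band, order, pad)
  }
  sm <- .as_signal_matrix(x)
  n <- nrow(sm$x)
  if (n < 2L) stop("need at least 2 samples")
  if (all(sm$x == 0))
    warning("all-zero signal: amplitude is zero and phase is meaningless")
  npad <- .pad_length(n, fs)
  Z <- .analytic_fft(.pad_signal(sm$x, npad, pad))
  Z <- Z[(npad + 1L):(npad + n), , drop = FALSE]
  amp <- Mod(Z); ph <- Arg(Z)
  if (sm$vec) { amp <- drop(amp); ph <- drop(ph) }
  structure(list(phase = ph, amplitude = amp, band = band, fs = fs),
            class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  n <- if (is.matrix(x$phase)) nrow(x$phase) else length(x$phase)
  m <- if (is.matrix(x$phase)) ncol(x$phase) else 1L
  cat(sprintf("<analytic_signal: %d samples x %d signal(s) @ %g Hz%s>\n",
              n, m, x$fs,
              if (!is.null(x$band)) paste0(", band ", format(x$band)) else ""))
  invisible(x)
}
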