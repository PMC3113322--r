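#' Filter specification
#'
#' Describes one of the three conditioning filters used in the pipeline:
#' a zero-phase brick-wall FFT high-pass (baseline-drift removal), a
#' zero-phase brick-wall FFT band-pass, or a zero-lag Butterworth low-pass.
#'
#' @param kind One of `"fft_highpass"`, `"fft_bandpass"`, `"butter_lowpass"`.
#' @param low_cut_hz Lower cutoff in Hz (high-pass and band-pass).
#' @param high_cut_hz Upper cutoff in Hz (band-pass and Butterworth low-pass).
#' @param order Filter order (Butterworth only; single-pass order, applied
#'   forward-backward for zero lag).
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(kind = c("fft_highpass", "fft_bandpass", "butter_lowpass"),
                        low_cut_hz = NULL, high_cut_hz = NULL, order = 4L) {
  kind <- match.arg(kind)
  if (kind %in% c("fft_highpass", "fft_bandpass")) {
    if (is.null(low_cut_hz) || low_cut_hz <= 0)
      stop("filter_spec: low_cut_hz must be positive")
  }
  if (kind %in% c("fft_bandpass", "butter_lowpass")) {
    if (is.null(high_cut_hz) || high_cut_hz <= 0)
      stop("filter_spec: high_cut_hz must be positive")
  }
  if (kind == "fft_bandpass" && low_cut_hz >= high_cut_hz)
    stop("filter_spec: band-pass requires low_cut_hz < high_cut_hz")
  if (kind == "butter_lowpass" && (!is.numeric(order) || order < 1))
    stop("filter_spec: order must be >= 1")
  structure(list(kind = kind, low_cut_hz = low_cut_hz,
                 high_cut_hz = high_cut_hz, order = as.integer(order)),
            class = "filter_spec")
}

#' Zero-phase brick-wall FFT filter
#'
#' Discrete Fourier transform, zero every bin whose frequency magnitude lies
#' outside the pass band (band edges inclusive), inverse transform.  Phase is
#' exactly preserved for retained bins, so the filter is zero-phase; output
#' length, sampling rate and start time are unchanged and the output is real.
#' A 0.3 Hz high-pass removes the slow baseline drift characteristic of
#' piezo-resistive textile sensors; the 0.3-4 Hz band-pass additionally
#' strips measurement noise above the frequency content of walking.
#'
#' @param x A [time_series()] with at least 8 samples.
#' @param spec A [filter_spec()] of kind `"fft_highpass"` or `"fft_bandpass"`.
#' @return Filtered [time_series()].
#' @examples
#' x <- time_series(3 + sin(2 * pi * seq(0, 10, by = 0.01)), fs_hz = 100)
#' y <- fft_filter(x, filter_spec("fft_bandpass", 0.3, 4))
#' max(abs(y$values - sin(2 * pi * seq(0, 10, by = 0.01)))) # ~0: DC removed
#' @export
fft_filter <- function(x, spec) {
  stopifnot(inherits(x, "gait_ts"), inherits(spec, "filter_spec"))
  if (!spec$kind %in% c("fft_highpass", "fft_bandpass"))
    stop("fft_filter: spec must be fft_highpass or fft_bandpass")
  n <- length(x$values)
  if (n < 8L) stop("fft_filter: need at least 8 samples")
  nyq <- x$fs_hz / 2
  lo <- spec$low_cut_hz
  hi <- if (spec$kind == "fft_bandpass") spec$high_cut_hz else nyq
  if (lo >= nyq) stop("fft_filter: low cutoff at or above Nyquist")
  if (spec$kind == "fft_bandpass" && spec$high_cut_hz >= nyq)
    stop("fft_filter: high cutoff at or above Nyquist")
  # bin k (0-based) has |frequency| = min(k, n - k) * fs / n
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * x$fs_hz / n
  eps <- 1e-9 * x$fs_hz   # edge bins are kept: inclusive pass band
  keep <- f >= lo - eps & f <= hi + eps
  X <- stats::fft(x$values)
  X[!keep] <- 0 + 0i
  time_series(Re(stats::fft(X, inverse = TRUE)) / n, x$fs_hz, x$t0_s)
}

# Butterworth low-pass coefficients via bilinear transform.
# wn = cutoff_hz / nyquist in (0, 1).  Returns list(b, a).
butter_lp_coeff <- function(order, wn) {
  warped <- tan(pi * wn / 2)
  k <- seq_len(order)
  # analog prototype poles on the left-half-plane unit circle, scaled
  p <- warped * exp(1i * (pi / 2 + pi * (2 * k - 1) / (2 * order)))
  gain <- Re(warped^order / prod(1 - p))
  pz <- (1 + p) / (1 - p)                      # bilinear, T = 2
  poly_from_roots <- function(r) {
    c0 <- 1 + 0i
    for (ri in r) c0 <- c(c0, 0) - c(0, c0 * ri)
    c0
  }
  b <- gain * Re(poly_from_roots(rep(-1 + 0i, order)))
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a)
}

# Steady-state initial state of the direct-form II transposed filter for a
# unit-amplitude step input: scaled by the first sample, it suppresses the
# start-up transient in forward-backward filtering.
iir_step_state <- function(b, a) {
  m <- max(length(b), length(a))
  b <- c(b, rep(0, m - length(b))) / a[1]
  a <- c(a, rep(0, m - length(a))) / a[1]
  n <- m - 1L
  A <- rbind(-a[2:m], cbind(diag(1, n - 1L), 0))
  solve(diag(1, n) - t(A), b[2:m] - a[2:m] * b[1])
}

# Direct-form II transposed IIR filtering with optional initial state.
iir_filter <- function(b, a, x, zi = NULL) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b); na <- length(a)
  m <- max(nb, na)
  b <- c(b, rep(0, m - nb)); a <- c(a, rep(0, m - na))
  n <- length(x)
  y <- numeric(n)
  z <- if (is.null(zi)) numeric(m - 1) else zi
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (m > 2) {
      z[1:(m - 2)] <- b[2:(m - 1)] * xi + z[2:(m - 1)] - a[2:(m - 1)] * yi
      z[m - 1] <- b[m] * xi - a[m] * yi
    } else {
      z[1] <- b[2] * xi - a[2] * yi
    }
    y[i] <- yi
  }
  y
}

#' Zero-lag Butterworth low-pass filter
#'
#' Forward-backward application of an order-`order` Butterworth low-pass
#' design, giving zero phase distortion (effective attenuation is the squared
#' single-pass magnitude response).  Endpoint transients are suppressed by
#' odd-reflection padding of length `3 * order` samples at each end, removed
#' after filtering; output length is preserved.  Used at 6 Hz on the
#' ankle-angle channel to stabilise the heel-lift minimum against
#' measurement noise.
#'
#' @param x A [time_series()].
#' @param cutoff_hz Cutoff frequency in Hz, in `(0, fs/2)`.
#' @param order Single-pass filter order (default 4).
#' @return Filtered [time_series()].
#' @export
butter_lowpass_zero_lag <- function(x, cutoff_hz, order = 4L) {
  stopifnot(inherits(x, "gait_ts"))
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= x$fs_hz / 2)
    stop("butter_lowpass_zero_lag: cutoff must lie in (0, fs/2)")
  if (!is.numeric(order) || order < 1)
    stop("butter_lowpass_zero_lag: order must be >= 1")
  order <- as.integer(order)
  co <- butter_lp_coeff(order, cutoff_hz / (x$fs_hz / 2))
  v <- x$values
  # reflective padding sized to the filter's time constant (3 x order
  # response lengths) so edge transients decay below 1e-6 and the
  # forward-backward pass is time-reversal symmetric to that level
  np <- min(ceiling(3 * order * x$fs_hz / cutoff_hz), length(v) - 1L)
  # odd (point-mirror) reflection about the end samples
  pre <- 2 * v[1] - v[(np + 1L):2L]
  post <- 2 * v[length(v)] - v[(length(v) - 1L):(length(v) - np)]
  vp <- c(pre, v, post)
  zi <- iir_step_state(co$b, co$a)
  y <- iir_filter(co$b, co$a, vp, zi * vp[1])
  y <- rev(iir_filter(co$b, co$a, rev(y), zi * y[length(y)]))
  time_series(y[(np + 1L):(np + length(v))], x$fs_hz, x$t0_s)
}

#' Resample a time series by linear interpolation
#'
#' Interpolates onto a uniform grid at `target_fs_hz` sharing the original
#' start time; the spanned duration is preserved to within one target sample.
#' Used to upsample the 100 Hz ankle-angle channel to the sensor's 1500 Hz
#' grid before comparison.
#'
#' @param x A [time_series()].
#' @param target_fs_hz Target sampling frequency in Hz.
#' @return A [time_series()] at `target_fs_hz`.
#' @export
resample_linear <- function(x, target_fs_hz) {
  stopifnot(inherits(x, "gait_ts"))
  if (!is.numeric(target_fs_hz) || target_fs_hz <= 0)
    stop("resample_linear: target_fs_hz must be positive")
  if (length(x$values) < 2L) stop("resample_linear: need at least 2 samples")
  span <- ts_duration(x)
  n_out <- floor(span * target_fs_hz + 1e-9) + 1L
  t_out <- x$t0_s + (seq_len(n_out) - 1L) / target_fs_hz
  v <- stats::approx(ts_times(x), x$values, xout = t_out, rule = 2)$y
  time_series(v, target_fs_hz, x$t0_s)
}

#' Scale one signal's peak-to-peak range to match another's
#'
#' Multiplies `x` by `ptp(reference) / ptp(x)`.  The scaling is purely
#' multiplicative — no offset shift — because the band-pass stage has already
#' removed the signal means.
#'
#' @param x [time_series()] to rescale.
#' @param reference [time_series()] supplying the target peak-to-peak range.
#' @return Rescaled [time_series()].
#' @export
scale_peak_to_peak <- function(x, reference) {
  stopifnot(inherits(x, "gait_ts"), inherits(reference, "gait_ts"))
  px <- ptp(x); pr <- ptp(reference)
  if (px == 0 || pr == 0)
    stop("scale_peak_to_peak: zero peak-to-peak range")
  time_series(x$values * (pr / px), x$fs_hz, x$t0_s)
}
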