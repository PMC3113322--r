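test_that("FFT filter removes DC and preserves in-band content", {
  # 1000 samples: the DFT period is exactly 10 s, so a 1 Hz sine sits on one bin
  t <- seq(0, 9.99, by = 0.01)
  hp <- filter_spec("fft_highpass", 0.3)
  bp <- filter_spec("fft_bandpass", 0.3, 4)

  const <- time_series(rep(2.5, length(t)), 100)
  expect_lt(max(abs(fft_filter(const, hp)$values)), 1e-10)

  sine <- sin(2 * pi * 1 * t)        # integer periods: sits on one DFT bin
  x <- time_series(sine, 100)
  expect_lt(max(abs(fft_filter(x, bp)$values - sine)), 1e-8)

  # linearity recovers the sine from a DC-offset composite
  y <- time_series(3 + sine, 100)
  expect_lt(max(abs(fft_filter(y, bp)$values - sine)), 1e-8)
})

test_that("FFT filter is idempotent and linear", {
  set.seed(11)
  bp <- filter_spec("fft_bandpass", 0.3, 4)
  x <- time_series(rnorm(512), 100)
  y <- time_series(rnorm(512), 100)
  fx <- fft_filter(x, bp)
  expect_lt(max(abs(fft_filter(fx, bp)$values - fx$values)), 1e-9)
  comb <- time_series(2 * x$values - 3 * y$values, 100)
  expect_lt(max(abs(fft_filter(comb, bp)$values -
                    (2 * fx$values - 3 * fft_filter(y, bp)$values))), 1e-9)
})

test_that("FFT filter rejects invalid specs and tiny inputs", {
  x <- time_series(rnorm(100), 100)
  expect_error(fft_filter(x, filter_spec("fft_highpass", 60)), "Nyquist")
  expect_error(fft_filter(time_series(1:4, 100),
                          filter_spec("fft_highpass", 0.3)), "8 samples")
  expect_error(filter_spec("fft_bandpass", 4, 0.3), "low_cut")
})

test_that("zero-lag Butterworth has unit DC gain, zero phase, strong stopband", {
  t <- seq(0, 5, by = 0.01)
  const <- time_series(rep(1.7, length(t)), 100)
  expect_lt(max(abs(butter_lowpass_zero_lag(const, 6)$values - 1.7)), 1e-8)

  # passband sine: < 1% attenuation, no phase shift at the peak
  s <- sin(2 * pi * 0.5 * t)
  y <- butter_lowpass_zero_lag(time_series(s, 100), 6)$values
  mid <- 100:400
  amp <- max(abs(y[mid]))
  expect_gt(amp, 0.99)
  # zero lag: cross-correlation peak at zero shift
  cc <- sapply(-5:5, function(k) cor(s[mid], y[mid + k]))
  expect_equal(which.max(cc), 6L)

  # stopband: 30 Hz sine at 6 Hz cutoff, order 4, forward-backward
  hf <- sin(2 * pi * 30 * t)
  yh <- butter_lowpass_zero_lag(time_series(hf, 100), 6, 4)$values
  expect_lt(sqrt(mean(yh[mid]^2)) / sqrt(mean(hf[mid]^2)), 0.05)
})

test_that("zero-lag Butterworth commutes with time reversal", {
  set.seed(21)
  x <- time_series(cumsum(rnorm(300)), 100)
  fwd <- butter_lowpass_zero_lag(x, 6)$values
  rev_in <- time_series(rev(x$values), 100)
  expect_lt(max(abs(rev(butter_lowpass_zero_lag(rev_in, 6)$values) - fwd)),
            1e-6)
})

test_that("linear resampling is exact on linear signals and accurate on sines", {
  ramp <- time_series(seq(0, 1, length.out = 101), 100)
  up <- resample_linear(ramp, 1500)
  expect_equal(up$fs_hz, 1500)
  expect_lt(max(abs(up$values - ts_times(up))), 1e-12)  # ramp(t) = t
  expect_lt(abs(ts_end(up) - ts_end(ramp)), 1 / 1500 + 1e-12)

  same <- resample_linear(ramp, 100)
  expect_equal(same$values, ramp$values)

  t <- seq(0, 2, by = 0.01)
  sine <- time_series(sin(2 * pi * t), 100)
  up2 <- resample_linear(sine, 1500)
  expect_lt(max(abs(up2$values - sin(2 * pi * ts_times(up2)))), 5e-4)
})

test_that("peak-to-peak scaling is multiplicative and exact", {
  t <- seq(0, 1, by = 0.01)
  x <- time_series(sin(2 * pi * t), 100)           # ptp 2
  ref2 <- time_series(c(rep(0, 50), rep(2, 51)), 100)
  expect_equal(scale_peak_to_peak(x, ref2)$values, x$values)

  ref4 <- time_series(c(rep(-2, 50), rep(2, 51)), 100)
  expect_lt(abs(ptp(scale_peak_to_peak(x, ref4)) - 4), 1e-12)

  set.seed(31)
  for (k in 1:100) {
    a <- time_series(rnorm(50), 10)
    b <- time_series(rnorm(50) * runif(1, 0.1, 10), 10)
    expect_lt(abs(ptp(scale_peak_to_peak(a, b)) - ptp(b)), 1e-9)
  }
  flat <- time_series(rep(1, 10), 10)
  expect_error(scale_peak_to_peak(x, flat), "zero peak-to-peak")
})
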