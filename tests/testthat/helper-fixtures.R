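# Shared fixtures: all synthetic, built in code at test time.

# A profile with every stochastic trial ingredient switched off, so trials
# are pure deterministic geometry (used for degenerate-recovery checks).
noiseless_profile <- function(condition = "sock_only", seed = 3,
                              mismatch = NULL) {
  p <- make_profile(condition, seed)
  p$noise_sd_v <- 0
  p$ankle_noise_sd_deg <- 0
  p$timing_jitter_sd_s <- 0
  p$drift_rate_v_per_s <- 0
  p$drift_sine_amp_v <- 0
  if (!is.null(mismatch)) p$kinematic_mismatch <- mismatch
  p
}

subject_trials <- function(profile, n = 10, seed_base = 0) {
  lapply(seq_len(n), function(j) {
    tr <- simulate_trial(profile, seed_base + j)
    tr$trial_index <- j
    tr
  })
}

# Two well-separated positive Gaussian bumps on a flat baseline; peaks at
# exactly t1 and t2 (both snapped to the grid).
two_bump_signal <- function(t1 = 1.0, t2 = 1.6, amp1 = 1, amp2 = 0.8,
                            w = 0.1, fs = 1500, dur = 2.5) {
  t <- seq(0, dur, by = 1 / fs)
  v <- amp1 * exp(-0.5 * ((t - t1) / w)^2) + amp2 * exp(-0.5 * ((t - t2) / w)^2)
  time_series(v, fs, 0)
}

# Brute-force scan oracles for the two search primitives: literal sample-by-
# sample loops, independent of the vectorised implementations they check.
oracle_find_p1 <- function(x, start_s, a1) {
  v <- x$values
  i0 <- which.min(abs(ts_times(x) - start_s))
  for (i in seq.int(max(i0 + 1L, 2L), length(v))) {
    if (v[i] > a1 && v[i] > v[i - 1L]) return(x$t0_s + (i - 1L) / x$fs_hz)
  }
  NA_real_
}

oracle_next_local_max <- function(x, from_s) {
  v <- x$values
  i0 <- max(which.min(abs(ts_times(x) - from_s)), 2L)
  for (i in seq.int(i0, length(v) - 1L)) {
    if (v[i] > v[i - 1L] && v[i] >= v[i + 1L])
      return(x$t0_s + (i - 1L) / x$fs_hz)
  }
  NA_real_
}

# Smooth random signal for oracle-equivalence sweeps.
random_smooth_signal <- function(n = 400, fs = 100) {
  v <- cumsum(stats::rnorm(n))
  v <- stats::filter(v, rep(1 / 7, 7), sides = 2)
  v[is.na(v)] <- 0
  time_series(as.numeric(v), fs, 0)
}
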