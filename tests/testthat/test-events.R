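test_that("find_p1 locates rising threshold crossings", {
  fs <- 100
  ramp <- time_series(seq(-1, 1, length.out = 201), fs)  # [0, 2] s
  t <- find_p1(ramp, 0, 0)
  expect_equal(t, 1.01)      # first sample strictly above zero
  expect_error(find_p1(ramp, 0, 2), class = "gaitsock_threshold_never_crossed")

  # two bumps straddling the threshold: crossing must be on bump 2
  x <- two_bump_signal(t1 = 1, t2 = 1.6, amp1 = 0.4, amp2 = 1)
  t2b <- find_p1(x, 0, 0.6)
  expect_equal(t2b, oracle_find_p1(x, 0, 0.6))
  expect_true(t2b > 1.3 && t2b < 1.6)
})

test_that("next_local_max matches the definition and fails on monotone input", {
  x <- two_bump_signal(t1 = 1, t2 = 1.6)
  expect_equal(next_local_max(x, 0), 1.0)
  expect_equal(next_local_max(x, 1.2), 1.6)
  mono <- time_series(seq_len(100), 100)
  expect_error(next_local_max(mono, 0), class = "gaitsock_no_maximum_found")
  # plateau resolves to its first sample
  plat <- time_series(c(0, 1, 2, 2, 2, 1, 0, 3, 0), 1)
  expect_equal(next_local_max(plat, 0), 2)
})

test_that("search primitives agree with brute-force oracles on random signals", {
  set.seed(101)
  for (k in 1:100) {
    x <- random_smooth_signal()
    a1 <- quantile(x$values, runif(1, 0.2, 0.9))
    got <- tryCatch(find_p1(x, 0.5, a1), gaitsock_detect_error = function(e) NA_real_)
    expect_identical(got, oracle_find_p1(x, 0.5, a1))
    from <- runif(1, 0, 2)
    gotm <- tryCatch(next_local_max(x, from), gaitsock_detect_error = function(e) NA_real_)
    expect_identical(gotm, oracle_next_local_max(x, from))
  }
})

test_that("detect_events walks the three stages on a hand-built signal", {
  x <- two_bump_signal(t1 = 1.0, t2 = 1.6)
  par <- algorithm_params(a1 = 0.3, a2 = 0, a3 = 0, a4 = 0.3, a5 = 0)
  det <- detect_events(x, par, search_start_s = 0, prepared = TRUE)
  expect_equal(det$hl_s, oracle_find_p1(x, 0, 0.3))
  expect_lt(abs(det$to_s - 1.0), 1 / 1500 + 1e-9)
  expect_lt(abs(det$hs_s - 1.6), 1 / 1500 + 1e-9)

  # a4 overrunning the signal is a stage failure
  par2 <- algorithm_params(0.3, 0, 0, 5, 0)
  expect_error(detect_events(x, par2, 0, prepared = TRUE),
               class = "gaitsock_no_maximum_found")
})

test_that("detector is DC-invariant and time-shift equivariant", {
  p <- make_profile("sock_only", 5)
  tr <- simulate_trial(p, 2)
  par <- calibrate(subject_trials(p, 5))
  d0 <- detect_events(tr$sensor, par, tr$truth$hs1_s)

  shifted <- time_series(tr$sensor$values + 0.7, 1500, tr$sensor$t0_s)
  d1 <- detect_events(shifted, par, tr$truth$hs1_s)
  expect_equal(d1$hl_s, d0$hl_s)
  expect_equal(d1$hs_s, d0$hs_s)

  lag <- time_series(tr$sensor$values, 1500, tr$sensor$t0_s + 0.25)
  d2 <- detect_events(lag, par, tr$truth$hs1_s + 0.25)
  for (f in c("hl_s", "to_s", "hs_s")) {
    expect_lt(abs(d2[[f]] - d0[[f]] - 0.25), 1 / 1500 + 1e-9)
  }
})

test_that("calibration reproduces truth on noiseless trials", {
  p <- noiseless_profile(seed = 1)
  trials <- subject_trials(p, 5)
  par <- calibrate(trials)
  for (tr in trials) {
    det <- detect_events(tr$sensor, par, tr$truth$hs1_s)
    expect_lt(abs(det$hl_s - tr$truth$hl_s), 1 / 1500 + 1e-9)
    expect_lt(abs(det$to_s - tr$truth$to_s), 1 / 1500 + 1e-9)
    expect_lt(abs(det$hs_s - tr$truth$hs2_s), 1 / 1500 + 1e-9)
  }
})

test_that("calibrated offsets are the means of per-trial offsets", {
  p <- make_profile("sock_only", 9)       # jitter SD 10 ms
  trials <- subject_trials(p, 5)
  par <- calibrate(trials)
  # recompute the per-trial anchors independently with the primitives
  offs <- sapply(trials, function(tr) {
    prep <- prepare_detection_signal(tr$sensor)
    to_pk <- next_local_max(prep, tr$truth$hl_s)
    hs_pk <- next_local_max(prep, tr$truth$hs2_s - 0.25 * (tr$truth$hs2_s - tr$truth$hs1_s))
    p1 <- find_p1(prep, tr$truth$hs1_s, par$a1)
    c(a2 = tr$truth$hl_s - p1, a3 = tr$truth$to_s - to_pk,
      a4h = hs_pk - to_pk, a5 = tr$truth$hs2_s - hs_pk)
  })
  expect_equal(par$a2, mean(offs["a2", ]), tolerance = 1e-9)
  expect_equal(par$a3, mean(offs["a3", ]), tolerance = 1e-9)
  expect_equal(par$a4, 0.5 * mean(offs["a4h", ]), tolerance = 1e-9)
  expect_equal(par$a5, mean(offs["a5", ]), tolerance = 1e-9)
})

test_that("a spurious 30% gait-cycle peak of TO magnitude defeats calibration", {
  p <- make_profile("shod", 4)
  p$spurious_peak <- TRUE
  p$spurious_amp_frac <- 1.1
  expect_error(calibrate(subject_trials(p, 5)),
               class = "gaitsock_calibration_infeasible")
  expect_error(calibrate(subject_trials(p, 5)), "calibration-infeasible")
})

test_that("prediction error grows monotonically with timing jitter", {
  seeds <- c(11, 12, 13)
  mean_err <- sapply(c(0, 0.005, 0.010, 0.020), function(j) {
    mean(sapply(seeds, function(sd) {
      p <- make_profile("sock_only", sd)
      p$timing_jitter_sd_s <- j
      rep <- evaluate_subject(subject_trials(p, 10))
      mean(rep$mean_abs_pct_gc)
    }))
  })
  expect_true(all(diff(mean_err) > 0))
})
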