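test_that("GRF segmentation finds the 5 N crossings", {
  fs <- 1500
  t <- seq(0, 3, by = 1 / fs)
  g1 <- time_series(ifelse(t >= 1.0 & t <= 1.6, 100, 0), fs)
  g2 <- time_series(ifelse(t >= 2.1, 100, 0), fs)
  seg <- segment_cycle_from_grf(g1, g2)
  expect_lt(abs(seg$hs1_s - 1.0), 1 / fs + 1e-9)
  expect_lt(abs(seg$to_s - 1.6), 1 / fs + 1e-9)
  expect_lt(abs(seg$hs2_s - 2.1), 1 / fs + 1e-9)

  weak <- time_series(ifelse(t > 1 & t < 2, 4, 0), fs)
  expect_error(segment_cycle_from_grf(weak, g2), "threshold")
  double <- time_series(ifelse((t > 0.5 & t < 1) | (t > 2 & t < 2.5), 50, 0), fs)
  expect_error(segment_cycle_from_grf(double, g2), "multiple")
})

test_that("GRF segmentation recovers generator truth exactly across seeds", {
  for (sd in seq(1, 400, by = 4)) {
    p <- make_profile(if (sd %% 2) "sock_only" else "shod", sd)
    tr <- simulate_trial(p, sd)
    seg <- segment_cycle_from_grf(tr$grf1, tr$grf2)
    expect_lt(abs(seg$hs1_s - tr$truth$hs1_s), 1 / 1500 + 1e-9)
    expect_lt(abs(seg$to_s - tr$truth$to_s), 1 / 1500 + 1e-9)
    expect_lt(abs(seg$hs2_s - tr$truth$hs2_s), 1 / 1500 + 1e-9)
  }
})

test_that("kinematic HL is the filtered ankle minimum just before toe off", {
  for (sd in c(3, 7, 20, 33)) {
    p <- noiseless_profile(seed = sd)
    tr <- simulate_trial(p, 1)
    hl <- true_hl_from_kinematics(tr$ankle, tr$truth$to_s)
    expect_lt(abs(hl - tr$truth$hl_s), 1 / tr$ankle$fs_hz + 1e-9)

    # 30 Hz noise at 10% of range is removed by the 6 Hz zero-lag filter
    noisy <- tr$ankle
    amp <- 0.1 * ptp(noisy)
    noisy$values <- noisy$values + amp * sin(2 * pi * 30 * ts_times(noisy))
    hl_n <- true_hl_from_kinematics(noisy, tr$truth$to_s)
    expect_lt(abs(hl_n - hl), 1 / tr$ankle$fs_hz + 1e-9)
  }
  mono <- time_series(seq(0, 10, by = 0.01), 100)
  expect_error(true_hl_from_kinematics(mono, 5), "no local minimum")
})

test_that("train/test evaluation is near-exact on degenerate subjects", {
  p <- noiseless_profile(seed = 2)
  rep <- evaluate_subject(subject_trials(p, 10))
  expect_false(rep$infeasible)
  expect_equal(rep$n_test_trials, 5)
  expect_true(all(rep$mean_abs_pct_gc < 0.1))
  # identical trials -> identical errors -> zero SD
  expect_true(all(rep$sd_pct_gc < 1e-9))
})

test_that("evaluation flags infeasible subjects and validates inputs", {
  p <- make_profile("shod", 4)
  p$spurious_peak <- TRUE
  p$spurious_amp_frac <- 1.1
  rep <- evaluate_subject(subject_trials(p, 10))
  expect_true(rep$infeasible)
  expect_null(rep$mean_abs_pct_gc)

  trials <- subject_trials(make_profile("sock_only", 1), 10)
  trials[[7]]$subject_id <- "other"
  expect_error(evaluate_subject(trials), "mix")
  expect_error(evaluate_subject(trials[1:4]), "more trials")
})

test_that("error percentages are invariant to uniform time dilation", {
  p <- make_profile("sock_only", 14)
  rep1 <- evaluate_subject(subject_trials(p, 10))
  p2 <- p
  k <- 1.15
  p2$cycle_duration_s <- p$cycle_duration_s * k
  p2$bump_widths_rise <- p$bump_widths_rise * k
  p2$bump_widths_fall <- p$bump_widths_fall * k
  p2$timing_jitter_sd_s <- p$timing_jitter_sd_s * k
  # not an exact replay (jitter draws differ in scale), but the error scale
  # in % gait cycle must be preserved within sampling noise
  rep2 <- evaluate_subject(subject_trials(p2, 10))
  expect_lt(abs(mean(rep2$mean_abs_pct_gc) - mean(rep1$mean_abs_pct_gc)), 1.0)
})

test_that("cohort_table aggregates subjects and renders dash rows", {
  p1 <- noiseless_profile(seed = 2); p1$subject_id <- "S01"
  p3 <- make_profile("sock_only", 16); p3$subject_id <- "S03"
  r1 <- evaluate_subject(subject_trials(p1, 10))
  r3 <- evaluate_subject(subject_trials(p3, 10))
  pbad <- make_profile("shod", 4)
  pbad$spurious_peak <- TRUE; pbad$spurious_amp_frac <- 1.1
  pbad$subject_id <- "S02"; pbad$condition <- "sock_only"
  r2 <- evaluate_subject(subject_trials(pbad, 10))

  tab1 <- cohort_table(list(r1))
  expect_equal(tab1$mean_hl[2], tab1$mean_hl[1])   # Average of one subject

  tab <- cohort_table(list(r1, r2, r3))
  expect_equal(nrow(tab), 4)
  expect_true(tab$infeasible[2])
  # Average over the two feasible subjects only
  expect_equal(tab$mean_hl[4], mean(c(tab$mean_hl[1], tab$mean_hl[3])))
  expect_equal(tab$mean_hs[4], mean(c(tab$mean_hs[1], tab$mean_hs[3])))

  lines <- render_cohort_table(tab)
  expect_match(lines[1], "Mean HL")
  expect_match(lines[3], "^S02(\t-){6}$")
  expect_error(cohort_table(list()), "empty")
})
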