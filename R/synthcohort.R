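#' Draw a synthetic subject profile
#'
#' Generates the per-subject parameters of the instrumented-sock signal
#' model.  The sensor waveform over one gait cycle is a sum of signed
#' asymmetric Gaussian bumps: maxima around heel strike (HS) and toe off
#' (TO), minima around heel lift (HL) and in mid-swing between TO and the
#' next HS.  Profiles encode the between-subject variability the sensor
#' exhibits: cycle duration (Normal(1.1 s, 0.1 s), truncated above 0.6 s),
#' peak-to-peak voltage (Uniform 0.2-0.4 V), asymmetric rise/fall bump widths
#' (a hysteresis-like signature of the knitted structure's viscoelasticity),
#' slow baseline drift (linear plus a 0.05 Hz sine), white measurement noise
#' at 5% of the subject's peak-to-peak range, trial-to-trial timing jitter of
#' the sensor features relative to the true events, and a `kinematic_mismatch`
#' coefficient in `[0, 1]` controlling how far the sensor shape diverges from
#' the ankle-angle signal.  The shod condition draws larger mismatch and
#' timing jitter, and with probability 0.05 a spurious positive peak at 30%
#' gait cycle of TO-peak magnitude — the documented failure mode that defeats
#' threshold-based calibration.
#'
#' @param condition `"sock_only"` or `"shod"`.
#' @param seed Non-negative integer seed; profiles are deterministic in
#'   `(condition, seed)`.
#' @return An object of class `"subject_profile"` (a named list).
#' @examples
#' p <- make_profile("sock_only", seed = 1)
#' p$ptp_v           # within [0.2, 0.4]
#' p$cycle_duration_s
#' @export
make_profile <- function(condition = c("sock_only", "shod"), seed) {
  condition <- match.arg(condition)
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0)
    stop("make_profile: seed must be a non-negative integer")
  with_local_seed(mix_seed(seed, 7L), {
    cyc <- stats::rnorm(1, 1.1, 0.1)
    while (cyc <= 0.6) cyc <- stats::rnorm(1, 1.1, 0.1)
    ptp_v <- stats::runif(1, 0.2, 0.4)
    # relative feature strengths (HS1, HL, TO, mid-swing, HS2), jittered per
    # subject then renormalised so the deepest trough-to-TO-peak span is ptp_v
    rel <- c(hs1 = 0.35, hl = 0.45, to = 0.55, mid = 0.35, hs2 = 0.35) *
      stats::runif(5, 0.85, 1.15)
    rel <- rel * ptp_v / (rel[["to"]] + rel[["hl"]])
    w_rise <- stats::runif(1, 0.055, 0.075)
    w_fall <- w_rise * stats::runif(1, 0.72, 0.90)
    mism <- if (condition == "shod") stats::runif(1, 0.25, 1.0)
            else stats::runif(1, 0.05, 0.60)
    spur <- condition == "shod" && stats::runif(1) < 0.05
    prof <- list(
      subject_id = sprintf("seed%d", as.integer(seed)),
      condition = condition,
      cycle_duration_s = cyc,
      ptp_v = ptp_v,
      bump_amplitudes = rel[c("hs1", "hl", "to", "hs2")],
      midswing_amplitude = rel[["mid"]],
      bump_widths_rise = rep(w_rise, 5),
      bump_widths_fall = rep(w_fall, 5),
      event_phases_pct = c(hs1 = 0, hl = 40, to = 60, mid = 80, hs2 = 100),
      drift_rate_v_per_s = stats::runif(1, -0.02, 0.02),
      drift_sine_amp_v = stats::runif(1, 0, 0.03),
      drift_sine_freq_hz = 0.05,
      noise_sd_v = 0.05 * ptp_v,
      timing_jitter_sd_s = if (condition == "shod") 0.015 else 0.010,
      kinematic_mismatch = mism,
      ankle_ptp_deg = stats::runif(1, 20, 30),
      ankle_noise_sd_deg = 0.2,
      # per-subject ankle divergence directions, engaged in proportion to
      # kinematic_mismatch; the HL trough is never phase-shifted so that the
      # kinematic ground-truth definition stays anchored
      ankle_phase_shift_s = c(stats::rnorm(1, 0, 0.08), 0, 0,
                              stats::rnorm(2, 0, 0.08)),
      # amplitude divergence is mild on the HL trough (index 2): that
      # feature defines the kinematic ground truth and must stay prominent
      ankle_amp_gamma = stats::rnorm(5, 0, c(0.6, 0.15, 0.6, 0.6, 0.6)),
      ankle_distort_amp = stats::runif(1, 0.15, 0.35),
      ankle_distort_phase = stats::runif(1, 0, 2 * pi),
      spurious_peak = spur,
      spurious_amp_frac = if (spur) stats::runif(1, 0.9, 1.1) else 0,
      body_weight_n = 9.81 * stats::rnorm(1, 72, 12)
    )
    class(prof) <- "subject_profile"
    validate_profile(prof)
    prof
  })
}

#' Validate a subject profile
#'
#' Checks the structural invariants of a [make_profile()] object; used
#' before every simulation so that hand-edited profiles (common in tests)
#' cannot produce ill-formed trials.
#'
#' @param profile A `"subject_profile"` object.
#' @return `profile`, invisibly; errors if an invariant fails.
#' @export
validate_profile <- function(profile) {
  p <- profile
  if (!p$condition %in% c("sock_only", "shod"))
    stop("profile: unknown condition label")
  if (p$cycle_duration_s <= 0) stop("profile: cycle_duration_s must be > 0")
  amps <- c(p$bump_amplitudes, p$midswing_amplitude)
  if (any(amps < 0)) stop("profile: bump amplitudes must be >= 0")
  if (any(c(p$bump_widths_rise, p$bump_widths_fall) <= 0))
    stop("profile: bump widths must be positive")
  if (any(c(p$noise_sd_v, p$timing_jitter_sd_s, p$ankle_noise_sd_deg) < 0))
    stop("profile: noise/jitter SDs must be >= 0")
  ph <- p$event_phases_pct
  if (length(ph) != 5L || any(diff(ph) <= 0) || ph[1] != 0 || ph[5] != 100)
    stop("profile: event_phases_pct must increase strictly from 0 to 100")
  if (p$kinematic_mismatch < 0 || p$kinematic_mismatch > 1)
    stop("profile: kinematic_mismatch must lie in [0, 1]")
  if (p$spurious_amp_frac < 0 || p$spurious_amp_frac > 1.2)
    stop("profile: spurious_amp_frac must lie in [0, 1.2]")
  invisible(profile)
}

#' Ground-truth gait event times
#'
#' @param hs1_s,hl_s,to_s,hs2_s Absolute event times in seconds; must be
#'   strictly increasing.
#' @return An object of class `"event_times"`.
#' @export
event_times <- function(hs1_s, hl_s, to_s, hs2_s) {
  t <- c(hs1_s, hl_s, to_s, hs2_s)
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    stop("event_times: times must be finite and strictly increasing")
  structure(list(hs1_s = unname(hs1_s), hl_s = unname(hl_s),
                 to_s = unname(to_s), hs2_s = unname(hs2_s)),
            class = "event_times")
}

# Asymmetric Gaussian bump: unit height at centre, width w_rise before it,
# w_fall after it.
asym_gauss <- function(t, centre, w_rise, w_fall) {
  w <- ifelse(t < centre, w_rise, w_fall)
  exp(-0.5 * ((t - centre) / w)^2)
}

# Signed feature template on a time grid.  centres/amps/signs are length-5
# (HS1, HL, TO, mid-swing, HS2).
feature_template <- function(t, centres, amps, w_rise, w_fall,
                             signs = c(1, -1, 1, -1, 1)) {
  v <- numeric(length(t))
  for (i in seq_along(centres)) {
    v <- v + signs[i] * amps[i] * asym_gauss(t, centres[i], w_rise[i], w_fall[i])
  }
  v
}

#' Simulate one walking trial
#'
#' Builds a single gait cycle plus 0.5 s lead-in/lead-out padding.  The
#' sensor channel (1500 Hz, volts) is the signed asymmetric-Gaussian feature
#' template evaluated at jittered feature times, plus linear drift, a slow
#' sine drift and white noise.  The ankle channel (100 Hz, degrees) is the
#' same template anchored at the *true* event times, with
#' `kinematic_mismatch`-proportional amplitude and phase perturbations and no
#' drift — its HL trough always sits at the true HL so that kinematic
#' ground-truth extraction is well defined.  Two vertical ground-reaction
#' force channels (1500 Hz, newtons) carry raised-sine stance envelopes whose
#' supra-5 N support is exactly `[HS1, TO]` for `grf1` and starts exactly at
#' `HS2` for `grf2`.  All true event times are snapped to the 1500 Hz grid.
#'
#' @param profile A [make_profile()] object (possibly hand-edited; it is
#'   re-validated).
#' @param trial_seed Integer seed; trials are deterministic in
#'   `(profile, trial_seed)`.
#' @return An object of class `"trial_record"`: sensor/ankle/grf1/grf2
#'   [time_series()] channels, `truth` ([event_times()]), and the
#'   `subject_id`, `condition`, `trial_index` labels.
#' @export
simulate_trial <- function(profile, trial_seed) {
  validate_profile(profile)
  p <- profile
  with_local_seed(mix_seed(trial_seed, 11L), {
    fs <- 1500
    fs_ankle <- 100
    pad <- 0.5
    jit <- p$timing_jitter_sd_s
    tcyc <- p$cycle_duration_s + stats::rnorm(1, 0, jit)
    tcyc <- max(tcyc, 0.5)
    snap <- function(t) round(t * fs) / fs

    # true event times on the sensor grid; HL is a kinematically defined
    # event, so its truth sits on the coarser ankle grid (a subset of the
    # sensor grid) where the trough minimum can actually be observed
    phases <- p$event_phases_pct / 100
    truth_all <- snap(pad + phases * tcyc)          # HS1 HL TO mid HS2
    truth_all[2] <- round(truth_all[2] * fs_ankle) / fs_ankle
    truth <- event_times(truth_all[1], truth_all[2], truth_all[3], truth_all[5])

    dur <- tcyc + 2 * pad
    n <- floor(dur * fs) + 1L
    t <- (seq_len(n) - 1L) / fs

    # sensor feature centres jitter independently around the true events
    centres <- truth_all + stats::rnorm(5, 0, jit)
    amps <- c(p$bump_amplitudes[["hs1"]], p$bump_amplitudes[["hl"]],
              p$bump_amplitudes[["to"]], p$midswing_amplitude,
              p$bump_amplitudes[["hs2"]])
    sensor <- feature_template(t, centres, amps,
                               p$bump_widths_rise, p$bump_widths_fall)
    if (isTRUE(p$spurious_peak)) {
      sp_c <- pad + 0.30 * tcyc + stats::rnorm(1, 0, jit)
      sensor <- sensor + p$spurious_amp_frac * p$bump_amplitudes[["to"]] *
        asym_gauss(t, sp_c, p$bump_widths_rise[3], p$bump_widths_fall[3])
    }
    sensor <- sensor + p$drift_rate_v_per_s * (t - dur / 2) +
      p$drift_sine_amp_v *
        sin(2 * pi * p$drift_sine_freq_hz * t + stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(n, 0, p$noise_sd_v)

    # Ankle channel: anchored at the *true* event times, with
    # mismatch-proportional divergence in swing-phase feature timing, all
    # feature amplitudes, and a slow additive distortion.  HL and TO keep
    # their true phases (stance kinematics define the ground truth), the
    # distortion is notched out around HL, and the ankle widths are
    # symmetric (the rise/fall skew is a viscoelastic artifact of the knitted
    # sensor, not of the joint angle) — together these keep the filtered
    # ankle trough within one ankle sample of the true HL at any mismatch
    # level.
    m <- p$kinematic_mismatch
    a_centres <- truth_all + m * p$ankle_phase_shift_s
    a_fac <- pmax(0.2, 1 + m * p$ankle_amp_gamma)
    a_scale <- p$ankle_ptp_deg / p$ptp_v
    w_sym <- (p$bump_widths_rise + p$bump_widths_fall) / 2
    n_a <- floor(dur * fs_ankle) + 1L
    t_a <- (seq_len(n_a) - 1L) / fs_ankle
    hl_notch <- 1 - exp(-0.5 * ((t_a - truth$hl_s) / 0.15)^2)
    ankle <- feature_template(t_a, a_centres, amps * a_fac * a_scale,
                              w_sym, w_sym) +
      hl_notch * m * p$ankle_distort_amp * p$ankle_ptp_deg *
        sin(2 * pi * 0.8 * t_a / tcyc + p$ankle_distort_phase) +
      stats::rnorm(n_a, 0, p$ankle_noise_sd_deg)

    # GRF stance envelopes: boundary samples sit at 6 N so the first/last
    # strictly-supra-5 N samples land exactly on the true events
    f_max <- 1.2 * p$body_weight_n
    stance_env <- function(tt, a, b) {
      v <- numeric(length(tt))
      on <- tt >= a - 1e-12 & tt <= b + 1e-12
      u <- (tt[on] - a) / (b - a)
      v[on] <- 6 + (f_max - 6) * sin(pi * u)
      v
    }
    stance_len <- truth$to_s - truth$hs1_s
    grf1 <- stance_env(t, truth$hs1_s, truth$to_s)
    grf2 <- stance_env(t, truth$hs2_s, min(truth$hs2_s + stance_len, t[n]))

    structure(list(
      sensor = time_series(sensor, fs, 0),
      ankle = time_series(ankle, fs_ankle, 0),
      grf1 = time_series(grf1, fs, 0),
      grf2 = time_series(grf2, fs, 0),
      truth = truth,
      subject_id = p$subject_id,
      condition = p$condition,
      trial_index = NA_integer_
    ), class = "trial_record")
  })
}

#' Simulate a cohort of subjects
#'
#' Draws `n_subjects` profiles and `n_trials` trials per subject.  Sub-seeds
#' are derived from the master seed and the subject/trial indices through a
#' fixed integer mixing function, so enlarging a cohort never reshuffles the
#' subjects already generated.
#'
#' @param n_subjects,n_trials Positive integers (the laboratory protocol
#'   used 20 subjects and 10 trials per condition).
#' @param condition `"sock_only"` or `"shod"`.
#' @param seed Master integer seed.
#' @return A list of class `"gait_cohort"` with one element per subject;
#'   each element is a list with `subject_id`, `profile` and `trials` (a list
#'   of [simulate_trial()] records).
#' @export
simulate_cohort <- function(n_subjects, n_trials,
                            condition = c("sock_only", "shod"), seed) {
  condition <- match.arg(condition)
  if (n_subjects < 1 || n_trials < 1)
    stop("simulate_cohort: counts must be positive")
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    prof <- make_profile(condition, mix_seed(seed, i, 0L))
    prof$subject_id <- sprintf("S%02d", i)
    trials <- vector("list", n_trials)
    for (j in seq_len(n_trials)) {
      tr <- simulate_trial(prof, mix_seed(seed, i, j))
      tr$trial_index <- j
      trials[[j]] <- tr
    }
    out[[i]] <- list(subject_id = prof$subject_id, profile = prof,
                     trials = trials)
  }
  class(out) <- "gait_cohort"
  out
}

#' Simulate a bench stretch-relax test of the knitted sensor
#'
#' Emulates the characterisation experiment in which a sensor sample is
#' repeatedly stretched and relaxed at a constant rate while its resistance
#' is recorded: a triangle-wave strain, and a resistance equal to a linear
#' gain on strain plus a decaying-exponential baseline drift, a
#' velocity-proportional asymmetry term (producing the hysteresis loop in
#' the raw resistance-strain plot), and white noise.  High-pass filtering
#' the resistance at 0.3 Hz removes the drift and recovers an approximately
#' linear resistance-strain relationship.
#'
#' @param rate_mm_s Stretch/relax rate in mm/s (bench protocol: 9 mm/s).
#' @param n_cycles Number of stretch-relax cycles.
#' @param seed Integer seed.
#' @param amplitude_mm Peak strain excursion (mm).
#' @param fs_hz Sampling rate of the bench recording.
#' @param gain_ohm_per_mm Linear resistance gain.
#' @param r0_ohm Relaxed-state resistance.
#' @param drift_amp_ohm Initial baseline-drift amplitude (decays towards 0).
#' @param drift_tau_s Drift time constant.
#' @param asym_ohm_s_per_mm Velocity-proportional hysteresis coefficient.
#' @param noise_sd_ohm Measurement noise SD.
#' @return An object of class `"stretch_bench"`: `strain_mm` and
#'   `resistance_ohm` [time_series()] at the same rate, plus `rate_mm_s`.
#' @export
simulate_stretch_test <- function(rate_mm_s, n_cycles, seed,
                                  amplitude_mm = 4.5, fs_hz = 100,
                                  gain_ohm_per_mm = 5, r0_ohm = 120,
                                  drift_amp_ohm = 8, drift_tau_s = 15,
                                  asym_ohm_s_per_mm = 0.15,
                                  noise_sd_ohm = 0.2) {
  if (rate_mm_s <= 0) stop("simulate_stretch_test: rate must be positive")
  if (n_cycles < 1) stop("simulate_stretch_test: n_cycles must be >= 1")
  with_local_seed(mix_seed(seed, 13L), {
    period <- 2 * amplitude_mm / rate_mm_s
    n <- floor(n_cycles * period * fs_hz) + 1L
    t <- (seq_len(n) - 1L) / fs_hz
    phase <- (t %% period) / period
    strain <- amplitude_mm * (1 - abs(2 * phase - 1))     # triangle 0..amp
    vel <- rate_mm_s * ifelse(phase < 0.5, 1, -1)
    resistance <- r0_ohm + gain_ohm_per_mm * strain +
      drift_amp_ohm * exp(-t / drift_tau_s) +
      asym_ohm_s_per_mm * vel +
      stats::rnorm(n, 0, noise_sd_ohm)
    structure(list(strain_mm = time_series(strain, fs_hz, 0),
                   resistance_ohm = time_series(resistance, fs_hz, 0),
                   rate_mm_s = rate_mm_s),
              class = "stretch_bench")
  })
}
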