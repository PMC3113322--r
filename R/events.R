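#' Detector parameters
#'
#' The five parameters of the peak-plus-offset gait event detector: a voltage
#' threshold `a1` on the conditioned sensor signal, signed time offsets `a2`
#' (threshold crossing to heel lift), `a3` (toe-off peak to toe off) and `a5`
#' (end-of-cycle peak to heel strike), and a positive advance time `a4` that
#' skips the mid-swing trough before the heel-strike peak search.  All time
#' parameters are fixed in seconds, not in % gait cycle, so the detector can
#' run on a raw voltage stream without knowing the cycle duration.
#'
#' @param a1 Threshold in volts (on the band-passed detection signal).
#' @param a2,a3,a5 Signed time offsets in seconds (negative values place the
#'   predicted event *before* its anchor feature).
#' @param a4 Advance time in seconds; must be positive.
#' @return An object of class `"algorithm_params"`.
#' @export
algorithm_params <- function(a1, a2, a3, a4, a5) {
  v <- c(a1, a2, a3, a4, a5)
  if (any(!is.finite(v))) stop("algorithm_params: parameters must be finite")
  if (a4 <= 0) stop("algorithm_params: a4 must be positive")
  structure(list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5),
            class = "algorithm_params")
}

#' @export
print.algorithm_params <- function(x, ...) {
  cat(sprintf("<detector params: a1=%.4g V, a2=%.4g s, a3=%.4g s, a4=%.4g s, a5=%.4g s>\n",
              x$a1, x$a2, x$a3, x$a4, x$a5))
  invisible(x)
}

#' Condition the sensor signal for event detection
#'
#' Applies the 0.3-4 Hz zero-phase FFT band-pass: the 0.3 Hz edge removes
#' the sensor's baseline drift, the 4 Hz edge removes measurement noise while
#' keeping the frequency content of walking.  No amplitude scaling is
#' applied — the detection threshold `a1` is specified in volts on this
#' signal.
#'
#' @param sensor Sensor [time_series()] (1500 Hz, volts).
#' @return Band-passed [time_series()], still in volts.
#' @export
prepare_detection_signal <- function(sensor) {
  fft_filter(sensor, filter_spec("fft_bandpass", 0.3, 4))
}

#' Find the first rising threshold crossing
#'
#' Returns the time of the first sample strictly after `start_s` whose value
#' exceeds `a1` while the signal is increasing (value above its predecessor).
#'
#' @param x A [time_series()] (the prepared detection signal).
#' @param start_s Search start time in seconds.
#' @param a1 Threshold in the signal's units.
#' @return Crossing time in seconds.  Errors with condition class
#'   `"gaitsock_threshold_never_crossed"` if no sample qualifies.
#' @export
find_p1 <- function(x, start_s, a1) {
  i0 <- ts_index_at(x, start_s)
  v <- x$values
  n <- length(v)
  if (i0 >= n) stop_detect("threshold-never-crossed",
                           "find_p1: search starts at end of signal")
  idx <- seq.int(max(i0 + 1L, 2L), n)
  hit <- idx[v[idx] > a1 & v[idx] > v[idx - 1L]]
  if (length(hit) == 0L)
    stop_detect("threshold-never-crossed",
                sprintf("find_p1: threshold %.4g never crossed on a rising edge", a1))
  x$t0_s + (hit[1L] - 1L) / x$fs_hz
}

#' Find the next local maximum
#'
#' Returns the time of the first sample at or after `from_s` that is a local
#' maximum: strictly above its predecessor and at or above its successor.  A
#' plateau of equal samples therefore resolves to its first sample, and the
#' signal endpoints are never maxima.
#'
#' @param x A [time_series()].
#' @param from_s Search start time in seconds.
#' @return Time of the maximum in seconds.  Errors with condition class
#'   `"gaitsock_no_maximum_found"` if the signal ends first.
#' @export
next_local_max <- function(x, from_s) {
  i0 <- max(ts_index_at(x, from_s), 2L)
  v <- x$values
  n <- length(v)
  if (i0 > n - 1L)
    stop_detect("no-maximum-found", "next_local_max: search starts at end of signal")
  idx <- seq.int(i0, n - 1L)
  hit <- idx[v[idx] > v[idx - 1L] & v[idx] >= v[idx + 1L]]
  if (length(hit) == 0L)
    stop_detect("no-maximum-found", "next_local_max: no local maximum before end of signal")
  x$t0_s + (hit[1L] - 1L) / x$fs_hz
}

stop_detect <- function(stage, msg) {
  cls <- paste0("gaitsock_", gsub("-", "_", stage))
  stop(structure(class = c(cls, "gaitsock_detect_error", "error", "condition"),
                 list(message = paste0("[", stage, "] ", msg), call = NULL)))
}

#' Detect heel lift, toe off and heel strike in one gait cycle
#'
#' The three-stage forward search, starting from the first heel strike:
#' \enumerate{
#'   \item Find the first point `P1` after `search_start_s` where the
#'     conditioned sensor signal is increasing and exceeds `a1`; heel lift is
#'     predicted at `P1 + a2`.
#'   \item Find the first local maximum after `P1` (the toe-off peak); toe
#'     off is predicted at that peak plus `a3`.
#'   \item Advance by `a4` (past the mid-swing trough) and find the next
#'     local maximum (the end-of-cycle peak); heel strike is predicted at
#'     that peak plus `a5`.
#' }
#' Offsets may be negative: the detector intentionally locates HL and TO
#' *behind* the corresponding sensor features, which is why it is a
#' retrospective rather than real-time method.
#'
#' @param sensor Raw sensor [time_series()] (1500 Hz, volts); conditioning
#'   via [prepare_detection_signal()] happens internally unless
#'   `prepared = TRUE`.
#' @param params An [algorithm_params()] object.
#' @param search_start_s Search start (the first heel strike) in seconds.
#' @param prepared Set `TRUE` if `sensor` has already been conditioned.
#' @return A list of class `"detection_result"` with predicted times `hl_s`,
#'   `to_s`, `hs_s` and anchor times `p1_s`, `to_peak_s`, `hs_peak_s`.
#' @export
detect_events <- function(sensor, params, search_start_s, prepared = FALSE) {
  stopifnot(inherits(params, "algorithm_params"))
  x <- if (prepared) sensor else prepare_detection_signal(sensor)
  p1 <- find_p1(x, search_start_s, params$a1)
  to_peak <- next_local_max(x, p1)
  if (to_peak + params$a4 > ts_end(x))
    stop_detect("no-maximum-found", "detect_events: a4 advance passes end of signal")
  hs_peak <- next_local_max(x, to_peak + params$a4)
  res <- list(hl_s = p1 + params$a2, to_s = to_peak + params$a3,
              hs_s = hs_peak + params$a5,
              p1_s = p1, to_peak_s = to_peak, hs_peak_s = hs_peak)
  pred <- c(res$hl_s, res$to_s, res$hs_s)
  if (any(pred < x$t0_s - 1e-9) || any(pred > ts_end(x) + 1e-9))
    stop_detect("prediction-outside-signal",
                "detect_events: a predicted event time falls outside the signal")
  structure(res, class = "detection_result")
}

# Per-trial calibration anchors on the prepared signal: the toe-off peak
# (first local max after true HL) and the end-of-cycle peak (first local max
# within +/- 25% cycle of true HS2).
calib_anchors <- function(prep, truth) {
  to_peak <- next_local_max(prep, truth$hl_s)
  cyc <- truth$hs2_s - truth$hs1_s
  win_lo <- max(truth$hs2_s - 0.25 * cyc, prep$t0_s)
  win_hi <- min(truth$hs2_s + 0.25 * cyc, ts_end(prep))
  hs_peak <- next_local_max(prep, win_lo)
  if (hs_peak > win_hi)
    stop_detect("no-maximum-found",
                "calibrate: no end-of-cycle peak within 25% cycle of true HS")
  list(to_peak = to_peak, hs_peak = hs_peak)
}

#' Calibrate the detector from training trials
#'
#' Automated parameter search from trials with known (ground-truth) event
#' times — in the laboratory protocol, the first five trials of each
#' subject/condition.  Per trial, the toe-off peak (first local maximum of
#' the prepared signal after true HL) and the end-of-cycle peak (first local
#' maximum within ±25% cycle of the true second heel strike) are located.
#' The threshold is set to the mean over trials of the midpoint between the
#' maximal signal value over the initial stages of the cycle (`[HS1, HL]`,
#' which contains the heel-strike peak) and the toe-off peak value: it must
#' clear every early-cycle maximum or `P1` fires at the search start, and
#' the midpoint maximises the remaining noise margin on the toe-off rising
#' edge.  The threshold is then verified on
#' every training trial: `P1` found with it must land on the rising edge of
#' that trial's toe-off peak; if not, the threshold is lowered in 10% steps,
#' at most five times, after which calibration is declared infeasible (the
#' documented failure mode when a spurious peak of toe-off magnitude sits at
#' ~30% gait cycle).  Finally `a2`, `a3` and `a5` are the mean signed
#' offsets between the true events and their anchors, and `a4` is half the
#' mean toe-off-peak-to-heel-strike-peak interval, which skips the mid-swing
#' trough while staying ahead of the heel-strike peak under moderate jitter.
#'
#' @param training A list of trial records (each with a `truth`
#'   [event_times()]) or, alternatively, a list of `list(trial, truth)`
#'   pairs; at least 2 trials.
#' @param truths Optional list of [event_times()] overriding the trials'
#'   own `truth` (used when truth is extracted from force plates and
#'   kinematics rather than taken from the generator).
#' @return An [algorithm_params()] object.  Errors with condition class
#'   `"gaitsock_calibration_infeasible"` when no workable threshold exists.
#' @export
calibrate <- function(training, truths = NULL) {
  if (length(training) < 2L)
    stop("calibrate: need at least 2 training trials")
  if (is.null(truths)) truths <- lapply(training, `[[`, "truth")
  preps <- lapply(training, function(tr) prepare_detection_signal(tr$sensor))
  anchors <- Map(calib_anchors, preps, truths)

  # The threshold must clear every maximum of the initial stages of the
  # cycle (the heel-strike peak, and any spurious early peak), otherwise P1
  # fires at the search start instead of on the toe-off rising edge.  So the
  # floor is the signal maximum on [HS1, HL], and a1 sits midway between
  # that floor and the toe-off peak.
  v_init <- mapply(function(p, tu) {
    max(p$values[ts_index_at(p, tu$hs1_s):ts_index_at(p, tu$hl_s)])
  }, preps, truths)
  v_pk <- mapply(function(p, an) ts_value_at(p, an$to_peak), preps, anchors)
  a1 <- mean(v_init + 0.5 * (v_pk - v_init))

  p1_on_edge <- function(a1) {
    vapply(seq_along(preps), function(k) {
      p1 <- tryCatch(find_p1(preps[[k]], truths[[k]]$hs1_s, a1),
                     gaitsock_detect_error = function(e) NA_real_)
      if (is.na(p1) || p1 > anchors[[k]]$to_peak + 1e-9) return(FALSE)
      pk <- tryCatch(next_local_max(preps[[k]], p1),
                     gaitsock_detect_error = function(e) NA_real_)
      !is.na(pk) &&
        abs(pk - anchors[[k]]$to_peak) <= 2 / preps[[k]]$fs_hz + 1e-9
    }, logical(1))
  }
  steps <- 0L
  while (!all(p1_on_edge(a1))) {
    steps <- steps + 1L
    if (steps > 5L)
      stop(structure(class = c("gaitsock_calibration_infeasible",
                               "error", "condition"),
                     list(message = paste("[calibration-infeasible] calibrate:",
                                          "no threshold places P1 on the toe-off",
                                          "rising edge in all training trials"),
                          call = NULL)))
    a1 <- a1 * 0.9
  }

  p1s <- mapply(function(p, tu) find_p1(p, tu$hs1_s, a1), preps, truths)
  a2 <- mean(mapply(function(tu, p1) tu$hl_s - p1, truths, p1s))
  a3 <- mean(mapply(function(tu, an) tu$to_s - an$to_peak, truths, anchors))
  a4 <- 0.5 * mean(vapply(anchors, function(an) an$hs_peak - an$to_peak,
                          numeric(1)))
  a5 <- mean(mapply(function(tu, an) tu$hs2_s - an$hs_peak, truths, anchors))
  algorithm_params(a1, a2, a3, a4, a5)
}
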