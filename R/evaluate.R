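#' Segment a gait cycle from two force-platform channels
#'
#' Heel strikes and toe off are defined by the vertical ground reaction
#' force crossing 5 N: HS1 is the time of the first `grf1` sample strictly
#' above 5 N, TO the time of the last such sample, and HS2 the time of the
#' first `grf2` sample strictly above 5 N.  Each channel must contain
#' exactly one contiguous supra-threshold episode.
#'
#' @param grf1,grf2 Vertical GRF [time_series()] (newtons) from the two
#'   force platforms.
#' @param threshold_n Force threshold in newtons (default 5).
#' @return A list with `hs1_s`, `to_s`, `hs2_s` (no HL: that event is
#'   defined kinematically).
#' @export
segment_cycle_from_grf <- function(grf1, grf2, threshold_n = 5) {
  episode <- function(g) {
    above <- g$values > threshold_n
    if (!any(above)) stop("segment_cycle_from_grf: no samples above threshold")
    runs <- rle(above)
    if (sum(runs$values) > 1L)
      stop("segment_cycle_from_grf: multiple supra-threshold episodes")
    i <- which(above)
    g$t0_s + (c(first = i[1L], last = i[length(i)]) - 1L) / g$fs_hz
  }
  e1 <- episode(grf1)
  e2 <- episode(grf2)
  list(hs1_s = unname(e1["first"]), to_s = unname(e1["last"]),
       hs2_s = unname(e2["first"]))
}

#' Kinematic heel-lift ground truth
#'
#' Heel lift is the point at which the ankle begins to plantarflex in
#' preparation for toe off: the last local minimum of the 6 Hz zero-lag
#' Butterworth-filtered ankle-angle signal strictly before toe off, searched
#' within the window `[to_s - window_s, to_s]`.
#'
#' @param ankle Ankle-angle [time_series()] (100 Hz, degrees).
#' @param to_s Toe-off time in seconds (from the force platform).
#' @param window_s Search window length before toe off (default 0.5 s,
#'   covering terminal stance at normal cadence).
#' @param cutoff_hz,order Low-pass settings (defaults 6 Hz, order 4).
#' @return Heel-lift time in seconds.
#' @export
true_hl_from_kinematics <- function(ankle, to_s, window_s = 0.5,
                                    cutoff_hz = 6, order = 4L) {
  if (to_s > ts_end(ankle) + 1e-9 || to_s < ankle$t0_s)
    stop("true_hl_from_kinematics: to_s outside signal")
  if (to_s - ankle$t0_s < 0.3)
    stop("true_hl_from_kinematics: need at least 0.3 s of signal before to_s")
  f <- butter_lowpass_zero_lag(ankle, cutoff_hz, order)
  i_hi <- ts_index_at(f, to_s, clamp = TRUE)
  i_lo <- max(ts_index_at(f, to_s - window_s, clamp = TRUE), 2L)
  v <- f$values
  idx <- seq.int(i_lo, i_hi - 1L)
  mins <- idx[v[idx] < v[idx - 1L] & v[idx] <= v[idx + 1L]]
  if (length(mins) == 0L)
    stop("true_hl_from_kinematics: no local minimum in window before to_s")
  f$t0_s + (mins[length(mins)] - 1L) / f$fs_hz
}

# Full ground-truth extraction for one trial, the way the laboratory
# pipeline derives it (force plates + filtered kinematics), independent of
# any generator-stored truth.
extract_truth <- function(trial, threshold_n = 5) {
  seg <- segment_cycle_from_grf(trial$grf1, trial$grf2, threshold_n)
  hl <- true_hl_from_kinematics(trial$ankle, seg$to_s)
  event_times(seg$hs1_s, hl, seg$to_s, seg$hs2_s)
}

#' Train/test evaluation of the detector for one subject
#'
#' The repeatability protocol: ground truth is extracted for every trial
#' from the force platforms and the filtered ankle signal (never from
#' generator metadata), the detector is calibrated on the first
#' `n_train` trials, and events are predicted on the remaining test trials.
#' Per event the signed error is `100 * (t_true - t_pred) / (HS2 - HS1)` in
#' % gait cycle of that test trial's own cycle; the report carries the mean
#' absolute error and the standard deviation of the signed error across test
#' trials.  If calibration is infeasible the report is flagged and carries
#' no error fields.
#'
#' @param trials Ordered list of trial records for one subject/condition
#'   (laboratory protocol: exactly 10, 5 train + 5 test).
#' @param n_train Number of leading trials used for calibration (default 5).
#' @return A list of class `"error_report"`: `subject_id`, `condition`,
#'   `infeasible`, `n_test_trials`, and per event `mean_abs_pct_gc` /
#'   `sd_pct_gc` named vectors over `c("HL", "TO", "HS")`, plus the fitted
#'   `params` and the per-trial signed errors in `errors_pct_gc`.
#' @export
evaluate_subject <- function(trials, n_train = 5L) {
  if (length(trials) <= n_train)
    stop("evaluate_subject: need more trials than n_train")
  ids <- unique(vapply(trials, `[[`, character(1), "subject_id"))
  conds <- unique(vapply(trials, `[[`, character(1), "condition"))
  if (length(ids) != 1L || length(conds) != 1L)
    stop("evaluate_subject: trials mix subjects or conditions")
  truths <- lapply(trials, extract_truth)
  train_idx <- seq_len(n_train)
  test_idx <- setdiff(seq_along(trials), train_idx)

  report <- list(subject_id = ids, condition = conds,
                 n_test_trials = length(test_idx), infeasible = FALSE,
                 mean_abs_pct_gc = NULL, sd_pct_gc = NULL,
                 params = NULL, errors_pct_gc = NULL)
  class(report) <- "error_report"

  params <- tryCatch(
    calibrate(trials[train_idx], truths[train_idx]),
    gaitsock_calibration_infeasible = function(e) NULL)
  if (is.null(params)) {
    report$infeasible <- TRUE
    return(report)
  }

  err <- matrix(NA_real_, nrow = length(test_idx), ncol = 3,
                dimnames = list(NULL, c("HL", "TO", "HS")))
  for (k in seq_along(test_idx)) {
    tr <- trials[[test_idx[k]]]
    tu <- truths[[test_idx[k]]]
    det <- detect_events(tr$sensor, params, tu$hs1_s)
    cyc <- tu$hs2_s - tu$hs1_s
    err[k, ] <- 100 * c(tu$hl_s - det$hl_s, tu$to_s - det$to_s,
                        tu$hs2_s - det$hs_s) / cyc
  }
  report$params <- params
  report$errors_pct_gc <- err
  report$mean_abs_pct_gc <- colMeans(abs(err))
  report$sd_pct_gc <- apply(err, 2, stats::sd)
  report
}

#' Evaluate every subject of a cohort
#'
#' @param cohort A [simulate_cohort()] object.
#' @param n_train Leading trials used for calibration (default 5).
#' @return A list of [evaluate_subject()] reports.
#' @export
evaluate_cohort <- function(cohort, n_train = 5L) {
  lapply(cohort, function(subj) evaluate_subject(subj$trials, n_train))
}

#' Cohort error table
#'
#' One row per subject with mean absolute error and SD of the signed error
#' (both in % gait cycle) for heel lift, toe off and heel strike, plus an
#' `"Average"` row over the subjects for which calibration was feasible.
#' Values are kept at full precision; rounding to one decimal happens only
#' in [render_cohort_table()].
#'
#' @param reports A non-empty list of [evaluate_subject()] reports.
#' @return A data.frame with columns `subject`, `mean_hl`, `sd_hl`,
#'   `mean_to`, `sd_to`, `mean_hs`, `sd_hs`, `infeasible`.
#' @export
cohort_table <- function(reports) {
  if (length(reports) == 0L) stop("cohort_table: empty input")
  row1 <- function(r) {
    if (r$infeasible) {
      data.frame(subject = r$subject_id, mean_hl = NA_real_, sd_hl = NA_real_,
                 mean_to = NA_real_, sd_to = NA_real_, mean_hs = NA_real_,
                 sd_hs = NA_real_, infeasible = TRUE, stringsAsFactors = FALSE)
    } else {
      m <- r$mean_abs_pct_gc; s <- r$sd_pct_gc
      data.frame(subject = r$subject_id, mean_hl = m[["HL"]], sd_hl = s[["HL"]],
                 mean_to = m[["TO"]], sd_to = s[["TO"]], mean_hs = m[["HS"]],
                 sd_hs = s[["HS"]], infeasible = FALSE, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, lapply(reports, row1))
  ok <- !tab$infeasible
  avg <- data.frame(subject = "Average",
                    mean_hl = mean(tab$mean_hl[ok]), sd_hl = mean(tab$sd_hl[ok]),
                    mean_to = mean(tab$mean_to[ok]), sd_to = mean(tab$sd_to[ok]),
                    mean_hs = mean(tab$mean_hs[ok]), sd_hs = mean(tab$sd_hs[ok]),
                    infeasible = FALSE, stringsAsFactors = FALSE)
  rbind(tab, avg)
}

#' Render a cohort error table as delimited text
#'
#' Values rounded to one decimal; infeasible subjects rendered as dash rows.
#'
#' @param tab A [cohort_table()] data.frame.
#' @param sep Column separator (default tab).
#' @return Character vector of lines (header first), invisibly also usable
#'   with [writeLines()].
#' @export
render_cohort_table <- function(tab, sep = "\t") {
  hdr <- paste(c("Subject", "Mean HL", "Std HL", "Mean TO", "Std TO",
                 "Mean HS", "Std HS"), collapse = sep)
  fmt <- function(x) ifelse(is.na(x), "-", formatC(round(x, 1), format = "fg"))
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    paste(c(tab$subject[i],
            fmt(unlist(tab[i, c("mean_hl", "sd_hl", "mean_to", "sd_to",
                                "mean_hs", "sd_hs")]))), collapse = sep)
  }, character(1))
  c(hdr, rows)
}
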