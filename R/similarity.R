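#' Pearson product-moment correlation
#'
#' @param a,b Equal-length numeric vectors (length >= 2), both non-constant.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("pearson_r: length mismatch")
  if (length(a) < 2L) stop("pearson_r: need at least 2 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("pearson_r: zero variance")
  stats::cor(a, b)
}

#' Normalised mean absolute deviation between two signals
#'
#' Each vector is scaled multiplicatively (no offset shift) to unit
#' peak-to-peak range, then `mean(|a_i - b_i|)` is returned.  Because the
#' scaling is multiplicative only, the statistic compares signal *variation*
#' irrespective of amplitude; means are assumed already removed by the
#' band-pass stage of the pipeline.
#'
#' @param a,b Equal-length numeric vectors with nonzero peak-to-peak range.
#' @return Non-negative scalar.
#' @examples
#' t <- seq(0, 1, length.out = 1001)
#' nmad(t, 1 - t)   # ~0.5: closed-form integral of |2t - 1|
#' @export
nmad <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("nmad: length mismatch")
  if (length(a) < 2L) stop("nmad: need at least 2 samples")
  pa <- max(a) - min(a); pb <- max(b) - min(b)
  if (pa == 0 || pb == 0) stop("nmad: zero peak-to-peak range")
  mean(abs(a / pa - b / pb))
}

#' Sensor-vs-kinematic similarity over one gait cycle
#'
#' Runs the comparison pipeline on a single cycle: slice the sensor and
#' ankle channels to the half-open interval `[HS1, HS2)`, upsample the ankle
#' channel to 1500 Hz, band-pass both at 0.3-4 Hz with the zero-phase FFT
#' filter, then compute [pearson_r()] and [nmad()] on the aligned pair.
#'
#' @param trial A [simulate_trial()] record (or any object with `sensor` and
#'   `ankle` [time_series()] channels).
#' @param cycle An [event_times()] giving the cycle boundaries; must lie
#'   within the trial span.
#' @return A list of class `"similarity_result"` with elements `r`, `nmad`
#'   and `n_samples`.
#' @export
compare_cycle <- function(trial, cycle) {
  stopifnot(inherits(cycle, "event_times"))
  if (cycle$hs1_s < trial$sensor$t0_s - 1e-9 ||
      cycle$hs2_s > ts_end(trial$sensor) + 1e-9)
    stop("compare_cycle: cycle outside trial span")
  sens <- ts_slice(trial$sensor, cycle$hs1_s, cycle$hs2_s, half_open = TRUE)
  ank <- ts_slice(trial$ankle, cycle$hs1_s, cycle$hs2_s, half_open = FALSE)
  ank <- resample_linear(ank, trial$sensor$fs_hz)
  n <- min(length(sens$values), length(ank$values))
  sens <- time_series(sens$values[seq_len(n)], sens$fs_hz, sens$t0_s)
  ank <- time_series(ank$values[seq_len(n)], ank$fs_hz, ank$t0_s)
  bp <- filter_spec("fft_bandpass", 0.3, 4)
  sv <- fft_filter(sens, bp)$values
  av <- fft_filter(ank, bp)$values
  structure(list(r = pearson_r(sv, av), nmad = nmad(sv, av), n_samples = n),
            class = "similarity_result")
}

#' Per-subject similarity: mean over gait cycles
#'
#' Arithmetic mean of `r` and of `nmad` over one gait cycle per trial
#' (the laboratory protocol averaged ten cycles, one from each walking
#' trial).
#'
#' @param trials A non-empty list of trial records; each must carry its
#'   cycle boundaries either as a `truth` element or supplied via `cycles`.
#' @param cycles Optional list of [event_times()], one per trial, overriding
#'   the trials' own `truth`.
#' @return A `"similarity_result"` with the averaged `r` and `nmad` and the
#'   total sample count.
#' @export
subject_similarity <- function(trials, cycles = NULL) {
  if (length(trials) == 0L) stop("subject_similarity: empty collection")
  if (is.null(cycles)) cycles <- lapply(trials, `[[`, "truth")
  res <- Map(compare_cycle, trials, cycles)
  structure(list(r = mean(vapply(res, `[[`, numeric(1), "r")),
                 nmad = mean(vapply(res, `[[`, numeric(1), "nmad")),
                 n_samples = sum(vapply(res, `[[`, numeric(1), "n_samples"))),
            class = "similarity_result")
}

#' Cohort similarity table
#'
#' One row per subject with the averaged Pearson correlation and nMAD for a
#' simulated cohort, mirroring the per-subject similarity summary of a
#' sensor-validation study.
#'
#' @param cohort A [simulate_cohort()] object.
#' @return A data.frame with columns `subject`, `r`, `nmad`, plus a final
#'   `"Mean"` row.
#' @export
similarity_table <- function(cohort) {
  rows <- lapply(cohort, function(subj) {
    s <- subject_similarity(subj$trials)
    data.frame(subject = subj$subject_id, r = s$r, nmad = s$nmad,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rbind(tab, data.frame(subject = "Mean", r = mean(tab$r),
                        nmad = mean(tab$nmad), stringsAsFactors = FALSE))
}
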