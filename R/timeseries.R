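#' Uniformly sampled time series
#'
#' The substrate of all signal math in gaitsock: an ordered vector of real
#' samples together with a sampling frequency and a start time.  Sample `i`
#' sits at time `t0_s + (i - 1) / fs_hz`.
#'
#' @param values Numeric vector of samples (at least 2, all finite).
#' @param fs_hz Sampling frequency in Hz (positive scalar).
#' @param t0_s Time of the first sample in seconds.
#'
#' @return An object of class `"gait_ts"`: a list with elements `values`,
#'   `fs_hz` and `t0_s`.
#' @examples
#' x <- time_series(sin(2 * pi * seq(0, 1, by = 0.01)), fs_hz = 100)
#' ts_duration(x)
#' @export
time_series <- function(values, fs_hz, t0_s = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("time_series: need at least 2 samples")
  if (anyNA(values) || any(!is.finite(values)))
    stop("time_series: values must be finite")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("time_series: fs_hz must be a positive scalar")
  structure(list(values = values, fs_hz = as.numeric(fs_hz),
                 t0_s = as.numeric(t0_s)),
            class = "gait_ts")
}

#' @export
print.gait_ts <- function(x, ...) {
  cat(sprintf("<time series: %d samples @ %g Hz, t = [%.4f, %.4f] s>\n",
              length(x$values), x$fs_hz, x$t0_s, ts_end(x)))
  invisible(x)
}

#' @export
length.gait_ts <- function(x) length(x$values)

#' Sample times of a time series
#' @param x A [time_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
ts_times <- function(x) x$t0_s + (seq_along(x$values) - 1) / x$fs_hz

#' Time of the last sample
#' @param x A [time_series()].
#' @return Scalar time in seconds.
#' @export
ts_end <- function(x) x$t0_s + (length(x$values) - 1) / x$fs_hz

#' Duration spanned by a time series
#' @param x A [time_series()].
#' @return `ts_end(x) - x$t0_s`, in seconds.
#' @export
ts_duration <- function(x) (length(x$values) - 1) / x$fs_hz

#' Index of the sample nearest a given time
#'
#' @param x A [time_series()].
#' @param t_s Time in seconds (vectorised).
#' @param clamp Clamp out-of-range times to the first/last sample instead of
#'   erroring.
#' @return Integer index (1-based).
#' @export
ts_index_at <- function(x, t_s, clamp = FALSE) {
  i <- as.integer(round((t_s - x$t0_s) * x$fs_hz)) + 1L
  if (clamp) {
    i <- pmax(1L, pmin(length(x$values), i))
  } else if (any(i < 1L | i > length(x$values))) {
    stop("ts_index_at: time outside signal span")
  }
  i
}

#' Value of the sample nearest a given time
#' @inheritParams ts_index_at
#' @return Numeric sample value(s).
#' @export
ts_value_at <- function(x, t_s) x$values[ts_index_at(x, t_s)]

#' Slice a time series between two times
#'
#' @param x A [time_series()].
#' @param from_s,to_s Slice boundaries in seconds.
#' @param half_open If `TRUE` the sample at `to_s` is excluded, giving the
#'   half-open interval `[from_s, to_s)` used for gait-cycle slices.
#' @return A [time_series()] whose `t0_s` is the time of the first retained
#'   sample.
#' @export
ts_slice <- function(x, from_s, to_s, half_open = FALSE) {
  if (to_s <= from_s) stop("ts_slice: to_s must exceed from_s")
  i0 <- ts_index_at(x, from_s)
  i1 <- ts_index_at(x, to_s)
  if (half_open) i1 <- i1 - 1L
  if (i1 - i0 + 1L < 2L) stop("ts_slice: slice has fewer than 2 samples")
  time_series(x$values[i0:i1], x$fs_hz, x$t0_s + (i0 - 1L) / x$fs_hz)
}

#' Peak-to-peak range of a numeric vector or time series
#' @param x A numeric vector or [time_series()].
#' @return `max(x) - min(x)`.
#' @export
ptp <- function(x) {
  v <- if (inherits(x, "gait_ts")) x$values else as.numeric(x)
  max(v) - min(v)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic integer mixing for sub-seed derivation: combines a master
# seed with stream indices so that cohorts are extensible (adding subjects
# or trials never reshuffles existing ones).  Kept below 2^31 - 1.
mix_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 3267000013 + 1013904223) %% 2147483647
  }
  as.integer(h)
}
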