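#' @name trial_io
#' @title Read and write trial files
#'
#' @description
#' A trial file is plain comma-delimited text with `#`-prefixed header lines
#' (`key=value`) followed by the data block with columns `time_s`,
#' `sensor_v`, `grf1_n`, `grf2_n`, `ankle_deg`.  The sensor and GRF channels
#' occupy every row of the 1500 Hz time grid; the ankle channel is sparse,
#' populated on every 15th row, preserving its true 100 Hz rate while
#' keeping all channels synchronised in one file.  Floating-point values are
#' rendered at full decimal precision (`%.17g`), so `write_trial()` followed
#' by `read_trial()` is the identity on every channel.  Synthetic trials
#' embed their ground-truth event times in the header; files without truth
#' keys (as a real recording would be) read back with `truth = NULL` and the
#' evaluation layer derives truth itself.
#'
#' @param trial A trial record (from [simulate_trial()] or [read_trial()]).
#' @param path File path.
#' @param extra_header Named character vector of additional header fields
#'   (e.g. the producing config hash and seed).
#' @return `read_trial()` returns a `"trial_record"`; `write_trial()`
#'   returns `path` invisibly.
NULL

fmt_num <- function(x) sprintf("%.17g", x)

#' @rdname trial_io
#' @export
write_trial <- function(trial, path, extra_header = character()) {
  s <- trial$sensor
  ratio <- as.integer(round(s$fs_hz / trial$ankle$fs_hz))
  hdr <- c(subject_id = trial$subject_id, condition = trial$condition,
           trial_index = as.character(trial$trial_index),
           fs_sensor_hz = fmt_num(s$fs_hz),
           fs_ankle_hz = fmt_num(trial$ankle$fs_hz),
           t0_s = fmt_num(s$t0_s))
  if (!is.null(trial$truth)) {
    tu <- trial$truth
    hdr <- c(hdr, truth_hs1_s = fmt_num(tu$hs1_s), truth_hl_s = fmt_num(tu$hl_s),
             truth_to_s = fmt_num(tu$to_s), truth_hs2_s = fmt_num(tu$hs2_s))
  }
  hdr <- c(hdr, extra_header)
  n <- length(s$values)
  ankle_col <- rep("", n)
  a_rows <- seq.int(1L, by = ratio, length.out = length(trial$ankle$values))
  if (max(a_rows) > n) stop("write_trial: ankle channel longer than time grid")
  ankle_col[a_rows] <- fmt_num(trial$ankle$values)
  lines <- c(paste0("# ", names(hdr), "=", hdr),
             "time_s,sensor_v,grf1_n,grf2_n,ankle_deg",
             paste(fmt_num(ts_times(s)), fmt_num(s$values),
                   fmt_num(trial$grf1$values), fmt_num(trial$grf2$values),
                   ankle_col, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

parse_header <- function(lines) {
  hl <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
  kv <- strsplit(hl, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) paste(p[-1], collapse = "="),
                         character(1)),
                  vapply(kv, `[[`, character(1), 1))
}

#' @rdname trial_io
#' @export
read_trial <- function(path) {
  lines <- readLines(path)
  hdr <- parse_header(lines)
  need <- c("subject_id", "condition", "trial_index", "fs_sensor_hz",
            "fs_ankle_hz", "t0_s")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("read_trial: malformed header, missing ", paste(miss, collapse = ", "))
  body <- lines[!startsWith(lines, "#")]
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  expect <- c("time_s", "sensor_v", "grf1_n", "grf2_n", "ankle_deg")
  miss <- setdiff(expect, cols)
  if (length(miss))
    stop("read_trial: missing column ", paste(miss, collapse = ", "))
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  nf <- lengths(rows)
  # a trailing empty ankle field drops in strsplit; pad it back
  rows[nf == length(cols) - 1L] <- lapply(rows[nf == length(cols) - 1L], c, "")
  if (any(lengths(rows) != length(cols)))
    stop("read_trial: ragged rows in data block")
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  t_s <- as.numeric(m[, "time_s"])
  if (any(diff(t_s) <= 0)) stop("read_trial: non-monotone time column")
  fs_s <- as.numeric(hdr["fs_sensor_hz"])
  fs_a <- as.numeric(hdr["fs_ankle_hz"])
  t0 <- as.numeric(hdr["t0_s"])
  ankle_raw <- m[, "ankle_deg"]
  ankle_v <- as.numeric(ankle_raw[ankle_raw != ""])
  truth <- NULL
  if (all(c("truth_hs1_s", "truth_hl_s", "truth_to_s", "truth_hs2_s")
          %in% names(hdr))) {
    truth <- event_times(as.numeric(hdr["truth_hs1_s"]),
                         as.numeric(hdr["truth_hl_s"]),
                         as.numeric(hdr["truth_to_s"]),
                         as.numeric(hdr["truth_hs2_s"]))
  }
  structure(list(
    sensor = time_series(as.numeric(m[, "sensor_v"]), fs_s, t0),
    ankle = time_series(ankle_v, fs_a, t0),
    grf1 = time_series(as.numeric(m[, "grf1_n"]), fs_s, t0),
    grf2 = time_series(as.numeric(m[, "grf2_n"]), fs_s, t0),
    truth = truth,
    subject_id = unname(hdr["subject_id"]),
    condition = unname(hdr["condition"]),
    trial_index = as.integer(hdr["trial_index"])
  ), class = "trial_record")
}

#' Read and write detector parameter files
#'
#' Flat `key=value` text: `a1` in volts, `a2`-`a5` in seconds, plus any
#' provenance header fields prefixed with `#`.
#'
#' @param params An [algorithm_params()] object.
#' @param path File path.
#' @param extra_header Named character vector of `#` header fields.
#' @return `read_params()` returns an [algorithm_params()];
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path, extra_header = character()) {
  lines <- c(if (length(extra_header))
               paste0("# ", names(extra_header), "=", extra_header),
             paste0(c("a1", "a2", "a3", "a4", "a5"), "=",
                    fmt_num(unlist(params[c("a1", "a2", "a3", "a4", "a5")]))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  kv <- parse_header(paste0("# ", lines[!startsWith(lines, "#")]))
  need <- c("a1", "a2", "a3", "a4", "a5")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("read_params: missing parameter ", paste(miss, collapse = ", "))
  v <- as.numeric(kv[need])
  algorithm_params(v[1], v[2], v[3], v[4], v[5])
}

#' Write a bench stretch test to a delimited file
#'
#' Three columns: `time_s`, `strain_mm`, `resistance_ohm`.
#'
#' @param bench A [simulate_stretch_test()] object.
#' @param path File path.
#' @param extra_header Named character vector of `#` header fields.
#' @return `path`, invisibly.
#' @export
write_stretch <- function(bench, path, extra_header = character()) {
  hdr <- c(rate_mm_s = fmt_num(bench$rate_mm_s), extra_header)
  lines <- c(paste0("# ", names(hdr), "=", hdr),
             "time_s,strain_mm,resistance_ohm",
             paste(fmt_num(ts_times(bench$strain_mm)),
                   fmt_num(bench$strain_mm$values),
                   fmt_num(bench$resistance_ohm$values), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

# FNV-1a hash of a string, rendered as 8 hex digits; used to stamp output
# artifacts with the configuration that produced them.  32-bit arithmetic is
# emulated in doubles (split multiply) so every step stays exact.
config_hash <- function(config) {
  s <- paste(names(config), unlist(config), sep = "=", collapse = ";")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- floor(h / 65536)
    h <- (((hi * 16777619) %% 65536) * 65536 + (h %% 65536) * 16777619) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run configuration
#'
#' Bundles the tunables of an end-to-end run and validates them against the
#' module preconditions.
#'
#' @param n_subjects,n_trials Cohort size (defaults 20 and 10).
#' @param condition `"sock_only"` or `"shod"`.
#' @param seed Master seed.
#' @param low_cut_hz,high_cut_hz Band-pass edges (defaults 0.3 and 4 Hz).
#' @param hl_cutoff_hz Kinematic low-pass cutoff for HL truth (default 6 Hz).
#' @param grf_threshold_n GRF event threshold (default 5 N).
#' @param out_dir Output directory.
#' @return A validated list of class `"run_config"` carrying its own hash.
#' @export
run_config <- function(n_subjects = 20L, n_trials = 10L,
                       condition = c("sock_only", "shod"), seed = 42L,
                       low_cut_hz = 0.3, high_cut_hz = 4, hl_cutoff_hz = 6,
                       grf_threshold_n = 5, out_dir = ".") {
  condition <- match.arg(condition)
  if (n_subjects < 1 || n_trials < 1) stop("run_config: counts must be positive")
  if (low_cut_hz <= 0 || high_cut_hz <= low_cut_hz)
    stop("run_config: need 0 < low_cut_hz < high_cut_hz")
  if (hl_cutoff_hz <= 0 || grf_threshold_n <= 0)
    stop("run_config: cutoff and threshold must be positive")
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials = as.integer(n_trials), condition = condition,
              seed = as.integer(seed), low_cut_hz = low_cut_hz,
              high_cut_hz = high_cut_hz, hl_cutoff_hz = hl_cutoff_hz,
              grf_threshold_n = grf_threshold_n, out_dir = out_dir)
  # the hash covers the scientific configuration only, not where it is
  # written, so identical runs into different directories stay comparable
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  class(cfg) <- "run_config"
  cfg
}
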