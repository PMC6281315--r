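#' Construct a recording
#'
#' A recording is a uniformly sampled time series with explicit units and an
#' explicit channel kind. Time is held internally as an integer sample index
#' plus a sampling rate; seconds appear only at the interface, which avoids
#' floating-point drift over minute-long traces.
#'
#' @param samples Numeric vector of samples. Units are volts for LFP channels,
#'   picoamperes for current channels and millivolts for voltage channels.
#' @param rate_hz Sampling rate in Hz (10000 for the recordings this package
#'   targets).
#' @param channel_kind One of `"lfp"`, `"current"`, `"voltage"`.
#' @param t0_s Start time of the first sample, seconds (>= 0).
#' @param label Free-text label.
#' @param condition Experimental condition tag: one of `"control"`, `"abeta"`,
#'   `"abeta_cp"`, `"abeta_cp_cz"`, `"other"`.
#' @return An object of class `gk_recording`.
#' @export
recording <- function(samples, rate_hz, channel_kind = c("lfp", "current", "voltage"),
                      t0_s = 0, label = "", condition = "other") {
  channel_kind <- match.arg(channel_kind)
  condition <- match.arg(condition, c("control", "abeta", "abeta_cp", "abeta_cp_cz", "other"))
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  if (t0_s < 0) stop("t0_s must be >= 0")
  structure(
    list(samples = samples, rate_hz = rate_hz, channel_kind = channel_kind,
         t0_s = t0_s, label = label, condition = condition),
    class = "gk_recording")
}

#' @export
print.gk_recording <- function(x, ...) {
  cat(sprintf("<gk_recording> %s | %s | %d samples @ %g Hz (%.2f s) | t0 = %g s | %s\n",
              x$channel_kind, rec_units(x), length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz, x$t0_s, x$condition))
  invisible(x)
}

# declared units per channel kind; never guessed from the data
rec_units <- function(rec) {
  switch(rec$channel_kind, lfp = "V", current = "pA", voltage = "mV")
}

#' Duration of a recording in seconds
#' @param rec A `gk_recording`.
#' @return Duration in seconds (n samples / rate).
#' @export
rec_duration <- function(rec) length(rec$samples) / rec$rate_hz

#' Extract a segment of a recording
#'
#' Windows are half-open `[start_s, start_s + dur_s)` relative to the
#' recording's own time axis, so contiguous segments tile the trace without
#' duplicating samples. Exactly `round(dur_s * rate_hz)` samples are returned.
#'
#' @param rec A `gk_recording`.
#' @param start_s Segment start, seconds from `t0_s`.
#' @param dur_s Segment duration, seconds (> 0).
#' @return A `gk_recording` covering the requested window.
#' @export
rec_segment <- function(rec, start_s, dur_s) {
  if (dur_s <= 0) stop("dur_s must be > 0")
  i0 <- round(start_s * rec$rate_hz)
  n <- round(dur_s * rec$rate_hz)
  if (i0 < 0 || i0 + n > length(rec$samples))
    stop(sprintf("segment [%g, %g) s not fully inside recording of %g s",
                 start_s, start_s + dur_s, rec_duration(rec)))
  recording(rec$samples[(i0 + 1L):(i0 + n)], rec$rate_hz, rec$channel_kind,
            t0_s = rec$t0_s + i0 / rec$rate_hz, label = rec$label,
            condition = rec$condition)
}

#' Construct a spike train
#'
#' @param times_s Strictly increasing spike times, seconds.
#' @param epoch Numeric length-2 `[start_s, end_s]` the spikes belong to.
#' @param source `"whole_cell"` or `"unit"`.
#' @param refractory_s Minimal admissible inter-spike interval (default 2 ms).
#' @return An object of class `gk_spike_train`.
#' @export
spike_train <- function(times_s, epoch = range(c(times_s, 0)), source = c("whole_cell", "unit"),
                        refractory_s = 0.002) {
  source <- match.arg(source)
  times_s <- as.numeric(times_s)
  if (is.unsorted(times_s, strictly = TRUE)) stop("spike times must be strictly increasing")
  if (length(times_s) && (min(times_s) < epoch[1] || max(times_s) > epoch[2]))
    stop("spike times outside epoch")
  if (length(times_s) > 1L && min(diff(times_s)) < refractory_s - 1e-12)
    stop(sprintf("inter-spike interval below refractory period (%g ms)", 1000 * refractory_s))
  structure(list(times_s = times_s, epoch = as.numeric(epoch), source = source),
            class = "gk_spike_train")
}

#' @export
print.gk_spike_train <- function(x, ...) {
  cat(sprintf("<gk_spike_train> %d spikes in [%g, %g] s (%s)\n",
              length(x$times_s), x$epoch[1], x$epoch[2], x$source))
  invisible(x)
}

#' Read a recording from CSV plus JSON sidecar
#'
#' The on-disk dialect is a two-column CSV (`time_s`, `value`) with a JSON
#' sidecar declaring at least `rate_hz`, `units` and `channel_kind`. The rate
#' inferred from the timestamps is cross-checked against the sidecar to a
#' relative tolerance of 1e-4; disagreement is a hard error, as is non-uniform
#' sampling.
#'
#' @param path_csv Path to the two-column CSV.
#' @param path_meta_json Path to the JSON sidecar.
#' @return A `gk_recording`.
#' @export
read_recording <- function(path_csv, path_meta_json) {
  dat <- utils::read.csv(path_csv)
  if (ncol(dat) < 2L) stop("recording CSV must have columns time_s, value")
  meta <- jsonlite::read_json(path_meta_json, simplifyVector = TRUE)
  if (is.null(meta$rate_hz) || is.null(meta$units) || is.null(meta$channel_kind))
    stop("sidecar must declare rate_hz, units and channel_kind")
  t <- dat[[1]]
  if (nrow(dat) >= 2L) {
    dt <- diff(t)
    if (max(dt) - min(dt) > 1e-4 * stats::median(dt))
      stop("non-uniform sampling in recording CSV")
    rate_csv <- 1 / stats::median(dt)
    if (abs(rate_csv - meta$rate_hz) > 1e-4 * meta$rate_hz)
      stop(sprintf("rate mismatch: sidecar declares %g Hz, CSV spacing implies %g Hz",
                   meta$rate_hz, rate_csv))
  }
  expected_units <- switch(meta$channel_kind, lfp = "V", current = "pA", voltage = "mV")
  if (!identical(meta$units, expected_units))
    stop(sprintf("units mismatch: sidecar declares '%s' but channel_kind '%s' requires '%s'",
                 meta$units, meta$channel_kind, expected_units))
  recording(dat[[2]], meta$rate_hz, meta$channel_kind,
            t0_s = if (nrow(dat)) t[1] else 0,
            label = meta$label %||% "", condition = meta$condition %||% "other")
}

#' Write a recording to CSV plus JSON sidecar
#'
#' @param rec A `gk_recording`.
#' @param path_csv,path_meta_json Output paths.
#' @return Invisibly, `path_csv`.
#' @export
write_recording <- function(rec, path_csv, path_meta_json) {
  t <- rec$t0_s + (seq_along(rec$samples) - 1L) / rec$rate_hz
  utils::write.csv(data.frame(time_s = t, value = rec$samples), path_csv, row.names = FALSE)
  jsonlite::write_json(
    list(rate_hz = rec$rate_hz, units = rec_units(rec), channel_kind = rec$channel_kind,
         label = rec$label, condition = rec$condition),
    path_meta_json, auto_unbox = TRUE, digits = NA)
  invisible(path_csv)
}

#' Read a spike train from a one-column CSV of seconds
#' @param path Path to CSV with a single column of spike times in seconds.
#' @param ... Passed to [spike_train()].
#' @return A `gk_spike_train`.
#' @export
read_spike_train <- function(path, ...) {
  dat <- utils::read.csv(path)
  spike_train(dat[[1]], ...)
}

#' Write a flat results table
#'
#' Results are flat records (metric, segment id, condition, value, units).
#' Values are written with full precision (`digits = 17`) so a round-trip read
#' reproduces reals to better than 1e-12 relative and integers exactly; column
#' order is fixed.
#'
#' @param results_table A data.frame of flat records.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results_table, path) {
  stopifnot(is.data.frame(results_table))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(format(results_table, digits = 17, scientific = NA, trim = TRUE),
                   con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_results <- function(path) utils::read.csv(path)

`%||%` <- function(a, b) if (is.null(a)) b else a

# local, restoring RNG scope: all synthesis is routed through this so a seed
# fixes output without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
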