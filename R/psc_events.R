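#' Detect postsynaptic current events
#'
#' Deterministic threshold detector for miniature/spontaneous synaptic
#' currents. The baseline is a running median (500 ms window); the
#' baseline-subtracted, polarity-rectified trace is lightly Gaussian-smoothed
#' and scanned for local maxima that rise by at least `amp_threshold_pA`
#' above the running minimum since the previous event (the local pre-event
#' floor). This catches events riding on the decay of a preceding event while
#' rejecting re-crossings of a decaying tail. The onset is the last sample
#' before the peak at which the trace sat at `floor + threshold` (the
#' threshold crossing); events whose onsets fall closer together than
#' `min_iei_ms` are merged into the first. Peak amplitude is read from the
#' unsmoothed trace at the detected peak, relative to the local floor, so
#' smoothing does not attenuate the reported amplitudes. Event supports are
#' truncated at the next event's onset, so per-event charges tile the trace
#' without double counting.
#'
#' @param rec A `gk_recording` of kind `"current"` (pA).
#' @param polarity `"inward"` (negative deflections, EPSC at -70 mV) or
#'   `"outward"` (positive deflections).
#' @param amp_threshold_pA Detection threshold: minimal rise above the local
#'   pre-event floor, pA (> 0).
#' @param min_iei_ms Minimal inter-event interval, ms (default 5).
#' @param baseline_win_s Running-median window, seconds (default 0.5).
#' @param smooth_lp_hz Gaussian pre-smoothing low-pass (-3 dB), Hz, applied
#'   before peak finding (default 1000; 0 disables).
#' @return A `gk_events`: data.frame with columns `onset_s`, `peak_s`,
#'   `peak_amplitude_pA` (signed per polarity), `charge_pC` (signed), plus
#'   attributes `polarity` and `rate_hz`.
#' @export
detect_psc <- function(rec, polarity = c("inward", "outward"), amp_threshold_pA,
                       min_iei_ms = 5, baseline_win_s = 0.5, smooth_lp_hz = 1000) {
  stopifnot(inherits(rec, "gk_recording"))
  polarity <- match.arg(polarity)
  if (rec$channel_kind != "current") stop("detect_psc expects a current recording")
  if (amp_threshold_pA <= 0) stop("amp_threshold_pA must be > 0")
  rate <- rec$rate_hz
  sgn <- if (polarity == "inward") -1 else 1
  k <- round(baseline_win_s * rate)
  if (k %% 2L == 0L) k <- k + 1L
  base <- stats::runmed(rec$samples, min(k, 2L * (length(rec$samples) %/% 2L) - 1L),
                        endrule = "median")
  d_raw <- sgn * (rec$samples - base) # rectified: events are positive excursions
  d <- if (smooth_lp_hz > 0 && smooth_lp_hz < rate / 2)
    gaussian_lowpass(d_raw, smooth_lp_hz, rate) else d_raw
  n <- length(d)
  if (max(d) < amp_threshold_pA) {
    if (max(-d) >= amp_threshold_pA) # excursions exist, but the other way
      warning("no events with the requested polarity; trace deflects the other way")
    return(empty_events(polarity, rate))
  }
  is_max <- d > c(-Inf, d[-n]) & d >= c(d[-1], -Inf)
  cand <- which(is_max & d >= amp_threshold_pA)
  min_iei_n <- min_iei_ms / 1000 * rate
  ev_on <- integer(0); ev_pk <- integer(0); ev_amp <- numeric(0)
  floor_val <- d[1]
  prev_i <- 1L
  last_on <- -Inf
  for (pk in cand) {
    floor_val <- min(floor_val, min(d[prev_i:pk]))
    prev_i <- pk
    if (d[pk] - floor_val < amp_threshold_pA) next
    level <- floor_val + amp_threshold_pA
    j <- pk
    while (j > 1L && d[j - 1L] > level) j <- j - 1L
    if (j - last_on < min_iei_n) { # merged into the previous event
      floor_val <- d[pk]
      next
    }
    ev_on <- c(ev_on, j); ev_pk <- c(ev_pk, pk)
    ev_amp <- c(ev_amp, d_raw[pk] - max(0, floor_val))
    last_on <- j
    floor_val <- d[pk]
  }
  if (!length(ev_on)) return(empty_events(polarity, rate))
  lim <- c(ev_on[-1] - 1L, n)
  ev_end <- vapply(seq_along(ev_on), function(e)
    event_end(d, ev_pk[e], lim[e]), integer(1))
  # support located on the smoothed trace; charge integrated on the raw one
  charge <- vapply(seq_along(ev_on), function(e) {
    seg <- d_raw[ev_on[e]:ev_end[e]]
    sum((seg[-1] + seg[-length(seg)]) / 2) / rate
  }, numeric(1))
  out <- data.frame(
    onset_s = rec$t0_s + (ev_on - 1L) / rate,
    peak_s = rec$t0_s + (ev_pk - 1L) / rate,
    end_s = rec$t0_s + (ev_end - 1L) / rate,
    peak_amplitude_pA = sgn * ev_amp,
    charge_pC = sgn * charge,
    truncated = ev_end == n & d[ev_end] > 0)
  structure(out, class = c("gk_events", "data.frame"),
            polarity = polarity, rate_hz = rate,
            epoch = c(rec$t0_s, rec$t0_s + rec_duration(rec)))
}

empty_events <- function(polarity, rate) {
  structure(data.frame(onset_s = numeric(0), peak_s = numeric(0),
                       peak_amplitude_pA = numeric(0), charge_pC = numeric(0)),
            class = c("gk_events", "data.frame"),
            polarity = polarity, rate_hz = rate, epoch = c(0, 0))
}

# end of an event's support: first non-positive sample after the peak
# (return to baseline), truncated at `lim` (the next event's onset or the
# record end) so event supports tile the trace without double counting
event_end <- function(d, pk, lim) {
  j <- pk
  while (j < lim && d[j + 1L] > 0) j <- j + 1L
  as.integer(j)
}

# trapezoidal integral of the rectified baseline-subtracted current over the
# event support [onset, return-to-baseline]; pA * s = pC
event_charge <- function(d, on, pk, rate, lim = length(d)) {
  seg <- d[on:event_end(d, pk, lim)]
  sum((seg[-1] + seg[-length(seg)]) / 2) / rate
}

#' Charge transfer of one detected event
#'
#' Trapezoidal integral of the baseline-subtracted current over
#' `[onset, return-to-baseline]`, in pC. This is the quantity stored per event
#' by [detect_psc()]; the helper recomputes it for a single onset so charge
#' can be audited against the trace.
#'
#' @param rec The `gk_recording` the event was detected on.
#' @param onset_s Event onset time, seconds.
#' @param polarity Event polarity as in [detect_psc()].
#' @param baseline_win_s Running-median window, seconds.
#' @param smooth_lp_hz Gaussian pre-smoothing as in [detect_psc()].
#' @return Signed charge, pC.
#' @export
charge_transfer <- function(rec, onset_s, polarity = c("inward", "outward"),
                            baseline_win_s = 0.5, smooth_lp_hz = 1000) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "inward") -1 else 1
  rate <- rec$rate_hz
  k <- round(baseline_win_s * rate)
  if (k %% 2L == 0L) k <- k + 1L
  base <- stats::runmed(rec$samples, min(k, 2L * (length(rec$samples) %/% 2L) - 1L),
                        endrule = "median")
  d_raw <- sgn * (rec$samples - base)
  d <- if (smooth_lp_hz > 0 && smooth_lp_hz < rate / 2)
    gaussian_lowpass(d_raw, smooth_lp_hz, rate) else d_raw
  on <- round((onset_s - rec$t0_s) * rate) + 1L
  # peak searched within 100 ms of the onset; support from the smoothed
  # trace, integral over the raw one
  hi <- min(length(d), on + round(0.1 * rate))
  pk <- on - 1L + which.max(d[on:hi])
  seg <- d_raw[on:event_end(d, pk, length(d))]
  sgn * sum((seg[-1] + seg[-length(seg)]) / 2) / rate
}

#' Per-minute summaries of a synaptic event series
#'
#' Half-open 1-min bins over the epoch; per bin: event frequency (count/60),
#' mean amplitude, mean inter-event interval and summed charge. The window
#' summary is the unweighted mean over complete bins.
#'
#' @param events A `gk_events` from [detect_psc()].
#' @param epoch Numeric length-2 `[start_s, end_s]`; defaults to the events'
#'   epoch attribute. Must span at least one complete bin.
#' @param bin_s Bin length, seconds (default 60).
#' @return A `gk_event_summary`: list with `per_bin` (data.frame) and
#'   `summary` (one-row data.frame of means over bins).
#' @export
summarize_events <- function(events, epoch = attr(events, "epoch"), bin_s = 60) {
  stopifnot(inherits(events, "gk_events"))
  dur <- epoch[2] - epoch[1]
  if (dur < bin_s) stop("epoch shorter than one complete bin")
  starts <- seq(epoch[1], epoch[2] - bin_s + 1e-9, by = bin_s)
  rows <- lapply(starts, function(s) {
    in_bin <- events$onset_s >= s & events$onset_s < s + bin_s
    onsets <- events$onset_s[in_bin]
    data.frame(
      bin_start_s = s,
      n_events = sum(in_bin),
      frequency_hz = sum(in_bin) / bin_s,
      mean_amplitude_pA = if (any(in_bin)) mean(events$peak_amplitude_pA[in_bin]) else NA_real_,
      mean_iei_s = if (sum(in_bin) > 1L) mean(diff(onsets)) else NA_real_,
      summed_charge_pC = sum(events$charge_pC[in_bin]))
  })
  per_bin <- do.call(rbind, rows)
  summary <- data.frame(
    frequency_hz = mean(per_bin$frequency_hz),
    mean_amplitude_pA = mean(per_bin$mean_amplitude_pA, na.rm = TRUE),
    mean_iei_s = mean(per_bin$mean_iei_s, na.rm = TRUE),
    summed_charge_pC = mean(per_bin$summed_charge_pC))
  structure(list(per_bin = per_bin, summary = summary), class = "gk_event_summary")
}

#' @export
print.gk_event_summary <- function(x, ...) {
  cat(sprintf("<gk_event_summary> %d bins; %.2f Hz, %.1f pA, IEI %.3f s, %.1f pC/bin\n",
              nrow(x$per_bin), x$summary$frequency_hz, x$summary$mean_amplitude_pA,
              x$summary$mean_iei_s, x$summary$summed_charge_pC))
  invisible(x)
}

#' Score detected events against a ground-truth list
#'
#' Greedy matching of detected onsets to true onsets within `tol_ms`.
#'
#' @param detected A `gk_events` (or data.frame with `onset_s`).
#' @param truth_onsets_s Numeric vector of true onset times, seconds.
#' @param tol_ms Matching tolerance, ms (default 2).
#' @return List with `recall`, `precision`, `n_matched`.
#' @export
score_detection <- function(detected, truth_onsets_s, tol_ms = 2) {
  det <- sort(detected$onset_s)
  truth <- sort(truth_onsets_s)
  tol <- tol_ms / 1000
  used <- logical(length(det))
  matched <- 0L
  for (t in truth) {
    cand <- which(!used & abs(det - t) <= tol)
    if (length(cand)) {
      used[cand[which.min(abs(det[cand] - t))]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(recall = if (length(truth)) matched / length(truth) else NA_real_,
       precision = if (length(det)) matched / length(det) else NA_real_,
       n_matched = matched)
}
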