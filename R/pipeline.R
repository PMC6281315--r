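#' Protocol configuration
#'
#' Bundles the analysis parameters of the three end-to-end protocols:
#' `"lfp_power_cr"` (integrated gamma power plus coefficient of rhythmicity on
#' 60-s LFP segments), `"spike_phase"` (concurrent LFP and spikes: firing
#' rate, preferred angle, half-width, Rayleigh gate) and `"psc"` (synaptic
#' event quantification in 1-min bins).
#'
#' @param protocol One of `"lfp_power_cr"`, `"spike_phase"`, `"psc"`.
#' @param power_band Integration band for gamma power, Hz (default 20-80).
#' @param cr_band Pre-filter band for the autocorrelogram, Hz (default 15-60).
#' @param phase_band Band for the instantaneous phase, Hz (default 20-60).
#' @param spike_threshold Spike detection threshold (mV), used when an epoch
#'   carries a voltage trace instead of a spike train.
#' @param psc_polarity,psc_threshold_pA PSC detector settings.
#' @param direction One-tailed test direction for treatment vs control
#'   (default `"less"`: treatment below control).
#' @param rayleigh_alpha Rayleigh inclusion gate (default 0.05).
#' @param seed Integer seed echoed into the report.
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(protocol = c("lfp_power_cr", "spike_phase", "psc"),
                            power_band = c(20, 80), cr_band = c(15, 60),
                            phase_band = c(20, 60), spike_threshold = -20,
                            psc_polarity = "inward", psc_threshold_pA = 5,
                            direction = "less", rayleigh_alpha = 0.05,
                            seed = 1L) {
  protocol <- match.arg(protocol)
  structure(list(protocol = protocol, power_band = power_band, cr_band = cr_band,
                 phase_band = phase_band, spike_threshold = spike_threshold,
                 psc_polarity = psc_polarity, psc_threshold_pA = psc_threshold_pA,
                 direction = direction, rayleigh_alpha = rayleigh_alpha,
                 seed = as.integer(seed)),
            class = "protocol_config")
}

#' Run an end-to-end protocol over a paired dataset
#'
#' For each recording the protocol's metrics are computed on the control and
#' the treatment epoch; metrics are then compared across recordings with the
#' one-tailed Wilcoxon matched-pairs test, summarised as mean +/- SEM and as
#' per-recording percent change. Recordings that cannot be analysed (missing
#' channel, Rayleigh gate failure, too few spikes) are excluded with a logged
#' reason, never silently. The report is fully determined by the dataset and
#' the configuration.
#'
#' @param config A [protocol_config()].
#' @param dataset A `gk_dataset` from [gen_experiment()], or any list of
#'   entries with `id` and `control`/`treatment` epochs.
#' @return A `gk_report`: list with `protocol`, `per_recording` (data.frame),
#'   `summary`, `tests`, `excluded` (data.frame of id + reason),
#'   `schema_version`, `seed`.
#' @export
run_protocol <- function(config, dataset) {
  stopifnot(inherits(config, "protocol_config"))
  metric_fun <- switch(config$protocol,
                       lfp_power_cr = epoch_metrics_lfp,
                       spike_phase = epoch_metrics_phase,
                       psc = epoch_metrics_psc)
  rows <- list()
  excluded <- list()
  for (entry in dataset) {
    res <- tryCatch({
      ctrl <- metric_fun(entry$control, config)
      trt <- metric_fun(entry$treatment, config)
      cbind(data.frame(id = entry$id), rename_prefix(ctrl, "control_"),
            rename_prefix(trt, "treatment_"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <- data.frame(id = entry$id,
                                                      reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  per_recording <- if (length(rows)) do.call(rbind, rows) else data.frame()
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(id = character(0), reason = character(0))
  metrics <- if (nrow(per_recording))
    sub("^control_", "", grep("^control_", names(per_recording), value = TRUE)) else character(0)
  # flags and per-recording p-values are reported but not group-compared
  metrics <- metrics[vapply(metrics, function(m)
    is.numeric(per_recording[[paste0("control_", m)]]) &&
      !is.logical(per_recording[[paste0("control_", m)]]) &&
      !grepl("_p$", m), logical(1))]
  tests <- list()
  summary_rows <- list()
  for (m in metrics) {
    b <- per_recording[[paste0("control_", m)]]
    a <- per_recording[[paste0("treatment_", m)]]
    ok <- is.finite(b) & is.finite(a)
    sm <- data.frame(metric = m,
                     control_mean = mean(b[ok]), control_sem = sem(b[ok]),
                     treatment_mean = mean(a[ok]), treatment_sem = sem(a[ok]),
                     n = sum(ok),
                     percent_change = mean(100 * (b[ok] - a[ok]) / b[ok]),
                     pooled_percent_change =
                       100 * (mean(b[ok]) - mean(a[ok])) / mean(b[ok]))
    summary_rows[[m]] <- sm
    tests[[m]] <- if (sum(ok) >= 5 && any(a[ok] != b[ok]))
      suppressWarnings(wilcoxon_one_tailed(b[ok], a[ok], direction = config$direction))
    else list(statistic = NA_real_, p = NA_real_, n = sum(ok), method = "not_run")
  }
  structure(list(protocol = config$protocol,
                 per_recording = per_recording,
                 summary = if (length(summary_rows)) do.call(rbind, summary_rows) else data.frame(),
                 tests = tests,
                 excluded = excluded,
                 n_excluded = nrow(excluded),
                 schema_version = "1.0",
                 seed = config$seed),
            class = "gk_report")
}

#' @export
print.gk_report <- function(x, ...) {
  cat(sprintf("<gk_report> protocol %s | n = %d recordings (%d excluded)\n",
              x$protocol, nrow(x$per_recording), x$n_excluded))
  if (nrow(x$summary)) {
    for (m in x$summary$metric) {
      s <- x$summary[x$summary$metric == m, ]
      p <- x$tests[[m]]$p
      cat(sprintf("  %-18s %.4g +/- %.3g -> %.4g +/- %.3g (%+.1f%% change), p = %s\n",
                  m, s$control_mean, s$control_sem, s$treatment_mean, s$treatment_sem,
                  -s$percent_change, format.pval(p, digits = 3)))
    }
  }
  if (x$n_excluded) {
    cat("  excluded:\n")
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("    %s: %s\n", x$excluded$id[i], x$excluded$reason[i]))
  }
  invisible(x)
}

# ---- per-epoch metric extractors -------------------------------------------

epoch_metrics_lfp <- function(epoch, config) {
  if (is.null(epoch$lfp)) stop("missing LFP channel")
  sp <- power_spectrum(epoch$lfp)
  gp <- integrated_power(sp, config$power_band[1], config$power_band[2])
  acg <- autocorrelogram(bandpass(epoch$lfp, config$cr_band[1], config$cr_band[2]))
  crr <- coefficient_of_rhythmicity(acg)
  data.frame(gamma_power_v2 = gp, cr = crr$cr,
             implied_freq_hz = crr$implied_freq_hz,
             freq_confirmed = confirm_frequency(crr, sp))
}

epoch_metrics_phase <- function(epoch, config) {
  if (is.null(epoch$lfp)) stop("missing LFP channel")
  spikes <- epoch$spikes
  if (is.null(spikes)) {
    if (is.null(epoch$voltage)) stop("missing spike train / voltage channel")
    spikes <- detect_spikes(epoch$voltage, config$spike_threshold)
  }
  if (length(spikes$times_s) < 5) stop("too few spikes (< 5)")
  ph <- spike_phases(spikes, instantaneous_phase(epoch$lfp,
                                                 config$phase_band[1],
                                                 config$phase_band[2]))
  dist <- phase_distribution(ph, alpha = config$rayleigh_alpha)
  if (!dist$included)
    stop(sprintf("uniform circular distribution (Rayleigh p = %.3g >= %.2g)",
                 dist$rayleigh_p, config$rayleigh_alpha))
  hw <- halfwidth(dist)
  sp <- power_spectrum(epoch$lfp)
  data.frame(gamma_power_v2 = integrated_power(sp, config$power_band[1], config$power_band[2]),
             firing_rate_hz = firing_rate(spikes)$rate_hz,
             preferred_angle_rad = dist$preferred_angle_rad,
             halfwidth_rad = hw$halfwidth_rad,
             rayleigh_p = dist$rayleigh_p)
}

epoch_metrics_psc <- function(epoch, config) {
  if (is.null(epoch$current)) stop("missing current channel")
  ev <- detect_psc(epoch$current, config$psc_polarity, config$psc_threshold_pA)
  if (!nrow(ev)) stop("no synaptic events detected")
  sm <- summarize_events(ev)$summary
  data.frame(frequency_hz = sm$frequency_hz,
             amplitude_pA = abs(sm$mean_amplitude_pA),
             iei_s = sm$mean_iei_s,
             charge_pC = abs(sm$summed_charge_pC))
}

rename_prefix <- function(df, prefix) {
  names(df) <- paste0(prefix, names(df))
  df
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Normalised time-course of a binned metric
#'
#' Checks bin contiguity (a gap is an error naming the missing bins), then
#' normalises the series to the mean of the leading control window via
#' [normalize_timecourse()].
#'
#' @param bin_start_s Bin start times, seconds.
#' @param values Per-bin metric values.
#' @param bin_s Bin length, seconds (default 60).
#' @param control_window Number of leading control bins (default 5).
#' @return Data.frame with `bin_start_s`, `value`, `normalized`.
#' @export
timecourse <- function(bin_start_s, values, bin_s = 60, control_window = 5L) {
  stopifnot(length(bin_start_s) == length(values))
  ord <- order(bin_start_s)
  bin_start_s <- bin_start_s[ord]
  values <- values[ord]
  expected <- seq(bin_start_s[1], by = bin_s, length.out =
                    round((bin_start_s[length(bin_start_s)] - bin_start_s[1]) / bin_s) + 1L)
  missing <- setdiff(round(expected, 6), round(bin_start_s, 6))
  if (length(missing))
    stop("gap in time-course bins; missing bin(s) at t = ",
         paste(missing, collapse = ", "), " s")
  data.frame(bin_start_s = bin_start_s, value = values,
             normalized = normalize_timecourse(values, control_window))
}

#' Serialise a report deterministically to JSON
#'
#' Identical dataset + configuration yield byte-identical JSON: no
#' timestamps, fixed field order, fixed numeric formatting.
#'
#' @param report A `gk_report`.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, na = "null", always_decimal = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
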