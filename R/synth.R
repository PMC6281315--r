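#' Simulation configuration for a gamma-band LFP
#'
#' The gamma component is a complex Ornstein-Uhlenbeck-modulated carrier:
#' `gamma(t) = gamma_sigma_v * sqrt(2) * Re(z(t) * exp(i*2*pi*f0*t))` with
#' `z` a unit-variance complex OU process of correlation time
#' `envelope_tau_s`. Its autocorrelation is exactly
#' `gamma_sigma_v^2 * exp(-tau/envelope_tau_s) * cos(2*pi*f0*tau)` — the
#' damped-cosine family — so `envelope_tau_s` is a closed-form handle on
#' rhythmicity and `gamma_sigma_v` is the RMS amplitude (hence the 20-80 Hz
#' integrated power is `gamma_sigma_v^2`). A `1/f^noise_exponent` Gaussian
#' background of RMS `noise_sigma_v` is added.
#'
#' @param rate_hz Sampling rate (default 10000).
#' @param dur_s Duration, seconds (>= 2).
#' @param f0_hz Gamma centre frequency (default 35 Hz).
#' @param envelope_tau_s Envelope correlation time (default 0.5 s).
#' @param gamma_sigma_v RMS of the gamma component, volts (default 30 uV,
#'   which puts 60-s integrated gamma power on the 1e-9 V^2 scale of
#'   interface-chamber recordings).
#' @param noise_exponent Spectral exponent beta of the background (default 1).
#' @param noise_sigma_v RMS of the background, volts (default 15 uV).
#' @param seed Integer seed; fixes the output exactly.
#' @return An `lfp_sim_config` list.
#' @export
lfp_sim_config <- function(rate_hz = 10000, dur_s = 60, f0_hz = 35,
                           envelope_tau_s = 0.5, gamma_sigma_v = 30e-6,
                           noise_exponent = 1, noise_sigma_v = 15e-6, seed = 1L) {
  stopifnot(rate_hz > 0, dur_s > 0, f0_hz > 0, envelope_tau_s > 0,
            gamma_sigma_v >= 0, noise_sigma_v >= 0)
  structure(list(rate_hz = rate_hz, dur_s = dur_s, f0_hz = f0_hz,
                 envelope_tau_s = envelope_tau_s, gamma_sigma_v = gamma_sigma_v,
                 noise_exponent = noise_exponent, noise_sigma_v = noise_sigma_v,
                 seed = as.integer(seed)),
            class = "lfp_sim_config")
}

#' Generate a synthetic gamma-band LFP recording
#'
#' @param cfg An [lfp_sim_config()].
#' @return A `gk_recording` of kind `"lfp"` (volts).
#' @export
gen_lfp <- function(cfg) {
  stopifnot(inherits(cfg, "lfp_sim_config"))
  if (cfg$dur_s < 2) stop("dur_s must be >= 2 s")
  n <- round(cfg$dur_s * cfg$rate_hz)
  with_seed(cfg$seed, {
    g <- if (cfg$gamma_sigma_v > 0) {
      z <- complex_ou(n, cfg$rate_hz, cfg$envelope_tau_s)
      t <- (0:(n - 1L)) / cfg$rate_hz
      cfg$gamma_sigma_v * sqrt(2) * Re(z * exp(2i * pi * cfg$f0_hz * t))
    } else numeric(n)
    b <- if (cfg$noise_sigma_v > 0)
      one_over_f_noise(n, cfg$noise_exponent, cfg$noise_sigma_v) else numeric(n)
    recording(g + b, cfg$rate_hz, "lfp", label = "synthetic gamma LFP")
  })
}

# stationary unit-variance complex AR(1)/OU process
complex_ou <- function(n, rate, tau) {
  a <- exp(-1 / (rate * tau))
  innov_sd <- sqrt((1 - a^2) / 2)
  re <- stats::rnorm(n, sd = innov_sd)
  im <- stats::rnorm(n, sd = innov_sd)
  z0 <- complex(real = stats::rnorm(1, sd = sqrt(0.5)),
                imaginary = stats::rnorm(1, sd = sqrt(0.5)))
  zr <- as.numeric(stats::filter(re, a, method = "recursive", init = Re(z0)))
  zi <- as.numeric(stats::filter(im, a, method = "recursive", init = Im(z0)))
  complex(real = zr, imaginary = zi)
}

# Gaussian 1/f^beta background via spectral shaping, scaled to RMS sigma
one_over_f_noise <- function(n, beta, sigma) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1L)) # DC bin excluded from scaling, then zeroed
  shape <- f^(-beta / 2)
  shape[1] <- 0
  # enforce conjugate symmetry of the shape (real output)
  k <- 1:(n - 1L)
  shape[1L + k] <- pmin(shape[1L + k], shape[1L + (n - k)])
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sigma / stats::sd(x)
}

#' Spike-train simulation configuration
#'
#' @param base_rate_hz Mean firing rate (default 2 Hz, the control pyramidal-
#'   cell rate in whole-cell recordings).
#' @param kappa Von Mises concentration of gamma phase locking (default 4).
#' @param mu_rad Preferred phase angle (default 5.2 rad, late-falling phase).
#' @param seed Integer seed.
#' @return A `spike_sim_config` list.
#' @export
spike_sim_config <- function(base_rate_hz = 2, kappa = 4, mu_rad = 5.2, seed = 1L) {
  stopifnot(base_rate_hz > 0, kappa >= 0)
  structure(list(base_rate_hz = base_rate_hz, kappa = kappa,
                 mu_rad = mu_rad %% (2 * pi), seed = as.integer(seed)),
            class = "spike_sim_config")
}

#' Generate a spike train phase-locked to a synthetic LFP
#'
#' Inhomogeneous Poisson process with von Mises intensity
#' `lambda(t) = base_rate * exp(kappa * cos(phi(t) - mu)) / I0(kappa)`, where
#' `phi` is the instantaneous gamma phase of the LFP (20-60 Hz band), sampled
#' by thinning. With `kappa = 0` the train is homogeneous Poisson and carries
#' no phase preference.
#'
#' @param lfp A `gk_recording` of kind `"lfp"`.
#' @param cfg A [spike_sim_config()].
#' @param refractory_ms Enforced minimal inter-spike interval (default 2 ms).
#' @return A `gk_spike_train`.
#' @export
gen_spikes_locked <- function(lfp, cfg, refractory_ms = 2) {
  stopifnot(inherits(lfp, "gk_recording"), inherits(cfg, "spike_sim_config"))
  dur <- rec_duration(lfp)
  if (cfg$base_rate_hz * dur < 20)
    warning("fewer than ~20 expected spikes; phase statistics will be unstable")
  phi <- instantaneous_phase(lfp, edge_trim_s = 0)$phase
  i0k <- besselI(cfg$kappa, 0)
  lam_max <- cfg$base_rate_hz * exp(cfg$kappa) / i0k
  with_seed(cfg$seed, {
    n_cand <- stats::rpois(1, lam_max * dur)
    cand <- sort(stats::runif(n_cand, 0, dur))
    idx <- pmin(length(phi), round(cand * lfp$rate_hz) + 1L)
    lam <- cfg$base_rate_hz * exp(cfg$kappa * cos(phi[idx] - cfg$mu_rad)) / i0k
    keep <- stats::runif(n_cand) < lam / lam_max
    times <- lfp$t0_s + cand[keep]
    # enforce refractoriness by dropping followers inside the dead time
    if (length(times) > 1L) {
      ref <- refractory_ms / 1000
      ok <- c(TRUE, diff(times) >= ref)
      while (!all(ok)) {
        times <- times[ok]
        ok <- c(TRUE, diff(times) >= ref)
      }
    }
    spike_train(times, epoch = c(lfp$t0_s, lfp$t0_s + dur),
                refractory_s = refractory_ms / 1000)
  })
}

#' Condition-level effect sizes for synthetic experiments
#'
#' Ratios applied to the generator between a control and a treatment epoch.
#' Defaults follow the acute whole-cell contrasts: gamma power scaled by 0.60
#' (a 40% reduction), spike-phase half-width widened by 1.30 (3.40 to 4.43
#' rad), firing rate scaled by 0.53 (the mean per-cell 47% reduction), and
#' PSC amplitude scaled by 0.77 (the 23% EPSC amplitude reduction).
#'
#' @param power_ratio Treatment/control gamma power (default 0.60).
#' @param halfwidth_factor Multiplier on the spike-phase half-width
#'   (default 1.30); implemented by scaling kappa by `1/halfwidth_factor^2`.
#' @param rate_ratio Treatment/control firing rate (default 0.53).
#' @param psc_amp_ratio Treatment/control PSC amplitude (default 0.77).
#' @param jitter_cv Lognormal coefficient of variation of the per-recording
#'   scale jitter (default 0.3).
#' @param seed Integer seed.
#' @return A `condition_effects` list.
#' @export
condition_effects <- function(power_ratio = 0.60, halfwidth_factor = 1.30,
                              rate_ratio = 0.53, psc_amp_ratio = 0.77,
                              jitter_cv = 0.3, seed = 1L) {
  stopifnot(power_ratio > 0, halfwidth_factor > 0, rate_ratio > 0, psc_amp_ratio > 0)
  structure(list(power_ratio = power_ratio, halfwidth_factor = halfwidth_factor,
                 rate_ratio = rate_ratio, psc_amp_ratio = psc_amp_ratio,
                 jitter_cv = jitter_cv, seed = as.integer(seed)),
            class = "condition_effects")
}

# ratios actually applied for each experimental condition: capsaicin rescue
# (abeta_cp) neutralises the effects, capsazepine (abeta_cp_cz) restores them
condition_ratios <- function(condition, effects) {
  switch(condition,
    control = list(power = 1, halfwidth = 1, rate = 1, psc_amp = 1),
    abeta = list(power = effects$power_ratio, halfwidth = effects$halfwidth_factor,
                 rate = effects$rate_ratio, psc_amp = effects$psc_amp_ratio),
    abeta_cp = list(power = 1, halfwidth = 1, rate = 1, psc_amp = 1),
    abeta_cp_cz = list(power = effects$power_ratio, halfwidth = effects$halfwidth_factor,
                       rate = effects$rate_ratio, psc_amp = effects$psc_amp_ratio),
    stop("unknown condition: ", condition))
}

#' Generate a synthetic PSC recording with ground truth
#'
#' Poisson event train; each event is a difference of exponentials
#' `A * (exp(-t/tau_decay) - exp(-t/tau_rise))`, peak-normalised so `A` is the
#' peak amplitude drawn from `N(amp_mean_pA, amp_sd_pA)`; additive white
#' Gaussian noise. Inward polarity (negative deflections).
#'
#' @param rate_hz Event rate, Hz.
#' @param amp_mean_pA,amp_sd_pA Peak amplitude distribution, pA.
#' @param tau_rise_ms,tau_decay_ms Kinetics (rise < decay), ms.
#' @param noise_sigma_pA White noise SD, pA.
#' @param dur_s Duration, seconds.
#' @param seed Integer seed.
#' @param sample_rate_hz Sampling rate (default 10000).
#' @return List with `recording` (a `gk_recording`, current in pA) and
#'   `truth` (data.frame of `onset_s`, `amp_pA`).
#' @export
gen_psc <- function(rate_hz = 20, amp_mean_pA = 25, amp_sd_pA = 5,
                    tau_rise_ms = 0.5, tau_decay_ms = 5, noise_sigma_pA = 2,
                    dur_s = 60, seed = 1L, sample_rate_hz = 10000) {
  if (!(tau_rise_ms < tau_decay_ms)) stop("tau_rise must be < tau_decay")
  if (tau_rise_ms < 0 || tau_decay_ms <= 0) stop("invalid kinetics")
  n <- round(dur_s * sample_rate_hz)
  with_seed(seed, {
    n_ev <- stats::rpois(1, rate_hz * dur_s)
    onsets <- sort(stats::runif(n_ev, 0, dur_s - 20 * tau_decay_ms / 1000))
    # events closer together than the detector's merge window (5 ms) are
    # unresolvable in principle; the generator does not produce them
    if (length(onsets) > 1L) {
      ok <- c(TRUE, diff(onsets) >= 0.005)
      while (!all(ok)) {
        onsets <- onsets[ok]
        ok <- c(TRUE, diff(onsets) >= 0.005)
      }
    }
    amps <- pmax(1, stats::rnorm(length(onsets), amp_mean_pA, amp_sd_pA))
    x <- numeric(n)
    kern_len <- round(10 * tau_decay_ms / 1000 * sample_rate_hz)
    tk <- (0:(kern_len - 1L)) / sample_rate_hz
    kern <- exp(-tk / (tau_decay_ms / 1000)) -
      (if (tau_rise_ms > 0) exp(-tk / (tau_rise_ms / 1000)) else as.numeric(tk == 0) * 0)
    kern <- kern / max(kern)
    for (e in seq_along(onsets)) {
      i0 <- round(onsets[e] * sample_rate_hz) + 1L
      ii <- i0:min(n, i0 + kern_len - 1L)
      x[ii] <- x[ii] - amps[e] * kern[seq_along(ii)] # inward: negative
    }
    if (noise_sigma_pA > 0) x <- x + stats::rnorm(n, sd = noise_sigma_pA)
    list(recording = recording(x, sample_rate_hz, "current", label = "synthetic PSC"),
         truth = data.frame(onset_s = onsets, amp_pA = amps))
  })
}

#' Generate a synthetic paired experiment
#'
#' For each of `n_recordings`, a control epoch and a treatment epoch are
#' generated with the treatment parameters scaled by the condition's effect
#' ratios; between-recording variability enters as lognormal scale jitter on
#' the per-recording baseline (CV from `effects$jitter_cv`). The same
#' per-recording jitter applies to both epochs, mirroring a paired design.
#'
#' @param condition One of `"control"`, `"abeta"`, `"abeta_cp"`,
#'   `"abeta_cp_cz"`.
#' @param effects A [condition_effects()].
#' @param n_recordings Number of paired recordings (default 10; fewer than 5
#'   triggers a warning).
#' @param protocol `"lfp_power_cr"` (LFP only), `"spike_phase"` (LFP + spike
#'   train) or `"psc"` (current trace + truth).
#' @param dur_s Epoch duration, seconds (default 60 for LFP, use >= 120 for
#'   spike-phase work).
#' @param seed Integer seed.
#' @param lfp_cfg Baseline LFP configuration (an [lfp_sim_config()]); its
#'   `dur_s`/`seed` fields are overridden per epoch.
#' @param spike_cfg Baseline spike configuration (a [spike_sim_config()]).
#' @return A `gk_dataset`: list of per-recording entries, each with `id`,
#'   `condition` and `control` / `treatment` epochs holding `lfp` and
#'   optionally `spikes`, `current`, `truth`.
#' @export
gen_experiment <- function(condition, effects = condition_effects(),
                           n_recordings = 10, protocol = "lfp_power_cr",
                           dur_s = 60, seed = 1L,
                           lfp_cfg = lfp_sim_config(),
                           spike_cfg = spike_sim_config()) {
  condition <- match.arg(condition, c("control", "abeta", "abeta_cp", "abeta_cp_cz"))
  protocol <- match.arg(protocol, c("lfp_power_cr", "spike_phase", "psc"))
  if (n_recordings < 5) warning("n_recordings < 5: comparisons will be underpowered")
  ratios <- condition_ratios(condition, effects)
  cv <- effects$jitter_cv
  sdlog <- sqrt(log(1 + cv^2))
  jit <- with_seed(seed, stats::rlnorm(n_recordings, -sdlog^2 / 2, sdlog))
  recs <- lapply(seq_len(n_recordings), function(r) {
    sub_seed <- (seed * 1009L + r * 7919L) %% .Machine$integer.max
    make_epoch <- function(which, scale) {
      eseed <- (sub_seed + if (which == "control") 0L else 500009L) %% .Machine$integer.max
      if (protocol == "psc") {
        sim <- gen_psc(amp_mean_pA = 25 * jit[r] * scale$psc_amp, dur_s = dur_s,
                       seed = eseed)
        list(current = sim$recording, truth = sim$truth)
      } else {
        cfg <- lfp_cfg
        cfg$dur_s <- dur_s
        cfg$seed <- eseed
        cfg$gamma_sigma_v <- lfp_cfg$gamma_sigma_v * sqrt(jit[r] * scale$power)
        cfg$noise_sigma_v <- lfp_cfg$noise_sigma_v * sqrt(jit[r])
        lfp <- gen_lfp(cfg)
        ep <- list(lfp = lfp)
        if (protocol == "spike_phase") {
          scfg <- spike_cfg
          scfg$seed <- (eseed + 104729L) %% .Machine$integer.max
          scfg$base_rate_hz <- spike_cfg$base_rate_hz * scale$rate
          scfg$kappa <- spike_cfg$kappa / scale$halfwidth^2
          ep$spikes <- gen_spikes_locked(lfp, scfg)
        }
        ep
      }
    }
    list(id = sprintf("rec%02d", r), condition = condition,
         control = make_epoch("control", condition_ratios("control", effects)),
         treatment = make_epoch("treatment", ratios))
  })
  structure(recs, class = "gk_dataset", condition = condition,
            protocol = protocol, dur_s = dur_s, seed = as.integer(seed))
}

#' @export
print.gk_dataset <- function(x, ...) {
  cat(sprintf("<gk_dataset> %d recordings | condition %s | protocol %s | %g s epochs\n",
              length(x), attr(x, "condition"), attr(x, "protocol"), attr(x, "dur_s")))
  invisible(x)
}
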