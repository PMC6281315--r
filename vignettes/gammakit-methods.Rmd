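---
title: "Quantifying gamma oscillations, spike-phase coupling and synaptic currents with gammakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gamma oscillations, spike-phase coupling and synaptic currents with gammakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammakit)
```

## The measurement problem

Kainate-activated hippocampal slices generate 20–80 Hz gamma oscillations in
area CA3 whose power and regularity degrade under amyloid-β, and recover
under TrpV1-receptor agonism. Quantifying that degradation requires four
measurements on sampled traces: the band-limited power of the LFP, the
regularity of the oscillation, the gamma-phase timing of pyramidal-cell
action potentials, and the amplitude/frequency/charge of postsynaptic
currents — followed by small-sample nonparametric comparisons between paired
(before/after drug) or unpaired (slice group vs slice group) conditions.
`gammakit` implements that chain end to end and ships a seeded synthetic
generator so each estimator is validated against inputs with known ground
truth.

All traces are `recording()` objects: uniformly sampled values with an
explicit rate, an explicit unit (V for LFP, pA for current, mV for membrane
potential) and a channel kind. Time is held as sample index plus rate;
seconds exist only at the interface, so minute-long windows carry no
floating-point drift. Segment windows are half-open `[start, start + dur)`
and therefore tile a recording without duplicating samples.

## Gamma band power

`power_spectrum()` computes averaged modified periodograms: 8192-sample
windows (~1.22 Hz bins at 10 kHz) advanced by half a window across a 60-s
segment, each Hann-tapered with the taper power normalised out. The per-bin
quantity is *total power* in V², defined so that the sum over all bins equals
the variance of the trace (Parseval; enforced by property test at 5%).
`integrated_power(sp, 20, 80)` is then literally a band sum, which is what
puts a 20 µV, 40 Hz sinusoid at `A²/2 = 2.0e-10` V² and interface-chamber
slice gamma on the 10⁻⁹ V² scale. A density view (V²/Hz) is available via
`power_density()`. Averaging and the Hann/50% overlap choice are our
variance-reduction convention; single-window FFT software produces the same
band sums within estimator variance. `spectrogram()` applies the same
estimator to sliding windows for time-resolved displays.

## Coefficient of rhythmicity

The 60-s segment used for power is band-passed 15–60 Hz — a single-pole RC
high-pass with its −3 dB point at 15 Hz applied forward-backward (zero
phase), then a symmetric Gaussian FIR low-pass with −3 dB at 60 Hz. Note the
cascade is not unity in the passband: at 40 Hz its analytic magnitude is
`bandpass_response(40, 15, 60)` ≈ 0.75. That attenuation cancels in the
normalised autocorrelogram, which is why the filter's job here is shaping,
not calibration.

`autocorrelogram()` returns the biased, lag-0-normalised autocorrelation over
±100 ms, and the affine rescale `r01 = (r + 1)/2`. The coefficient of
rhythmicity is

> Cr = (α − β)/(α + β),

with β the value of `r01` at its first trough after lag 0 and α at the next
(second) peak — one gamma period out, so `1000/peak_lag_ms` is an implied
frequency that `confirm_frequency()` checks against the spectral peak (5 Hz
default tolerance). The rescale to `[0, 1]` is what makes Cr land in `[0, 1]`
with signed correlation troughs; without it a strongly rhythmic trace
(trough near −1) would make the denominator vanish. Extrema are *located* on
a 1-ms-smoothed copy of `r01` (ties toward the smaller lag) but α and β are
*read* from the raw curve at the located lags, so the smoothing suppresses
sample-level jitter without biasing values; on closed-form damped-cosine
autocorrelograms `r(τ) = e^{−τ/τd}·cos(2π·40τ)` the extraction matches the
analytic extrema to 10⁻³ (the analytic peak of a damped cosine sits slightly
*before* the full period — 1.5 ms early at τd = 10 ms — which the tests
account for by optimising the closed form rather than evaluating it at 25 ms).
A trace with no local extrema inside 100 ms gets Cr = 0 and
`rhythmic = FALSE` rather than an error. The rhythmicity flag threshold
defaults to the printed convention Cr ≥ 0.01 and is configurable; we note it
is surprisingly permissive (0.1 would be a more discriminating cut) and we
surface Cr itself everywhere rather than the flag.

## Spike-phase coupling

`instantaneous_phase()` band-passes the LFP 20–60 Hz with the same zero-phase
cascade, takes the angle of the FFT-based Hilbert analytic signal, and wraps
it to `[0, 2π)` with the oscillation peak at 0 and trough at π. The first and
last 500 ms are invalidated (`NA`) to keep transform edge artefacts out;
spikes landing there are dropped and counted. Phase lookup is at the nearest
sample: at 10 kHz the worst-case error for a 60 Hz rhythm is
2π·60·5×10⁻⁵ ≈ 0.019 rad, far below any effect of interest.

Spikes come either from `detect_spikes()` (amplitude threshold, first
suprathreshold crossing, 2 ms refractory merge) or as precomputed spike
trains. Each cell's phase sample is gated by the Rayleigh test — resultant
length R with the standard analytic p-approximation — and only cells with a
non-uniform distribution (p < 0.05) are analysed further; exclusions are
reported with reasons, never silent. The preferred angle is the circular mean
(`atan2(ΣsinΦ, ΣcosΦ)`), not the fitted Gaussian centre, which is more robust
to fit failures; the fitted centre is reported alongside.

The synchrony measure is the half-width of the firing window: the spike-phase
histogram (36 bins of 10°, peak-normalised — FWHM is scale invariant and the
fit is better conditioned) is rotated so the circular mean sits at the domain
centre, and `a·G(θ; μ, σ) + c` is fitted by Levenberg–Marquardt, where `G`
is a Gaussian evaluated together with its two adjacent period images. The
period images matter: for wide windows (σ ≳ 1.2 rad) a plain Gaussian lets
the baseline term absorb the wrapped tails and deflates σ by ~10%. The
half-width is the *full* width at half maximum, `2√(2 ln 2)·σ`, capped at 2π
— half-widths of 3.4–5 rad on a 2π support are only meaningful as FWHM. The
baseline offset `c` reflects genuine baseline firing in real cells. If the
fit fails to converge the direct histogram FWHM is substituted and flagged in
the `method` field. Recovery is calibrated on wrapped-normal samples:
across σ ∈ {0.5, 1.0, 1.5} rad (n = 2000 spikes) the mean estimate is within
7% of 2.355σ and monotone in σ, with a mild (~5%) downward bias remaining at
σ = 1.5 where the distribution is nearly uniform.

## Synaptic events

`detect_psc()` is a deterministic threshold detector for spontaneous
synaptic currents. The baseline is a 500-ms running median; the
baseline-subtracted, polarity-rectified trace is lightly Gaussian-smoothed
(−3 dB 1 kHz) and scanned for local maxima that rise at least the threshold
above the running minimum since the previous event. The local-floor criterion
is what separates two realities of these recordings: events riding on the
decay of a predecessor (detected, because the rise from the decaying floor is
large) and noise re-crossings of a decaying tail (rejected, because the rise
from the floor is small). Amplitude is read from the *unsmoothed* trace at
the detected peak relative to the local floor, so smoothing never attenuates
reported amplitudes; charge is the trapezoidal integral of the raw
baseline-subtracted current over the event support, which is truncated at the
next event's onset so per-event charges tile the trace without double
counting (events truncated by the record end are flagged). Onsets closer than
5 ms are merged into the first. `summarize_events()` bins half-open 1-min
windows: frequency (count/60), mean amplitude, mean inter-event interval and
summed charge per bin, with the window summary the unweighted mean over
complete bins. Charge transfer is reported both as the per-bin sum (the
convention that puts it on the hundreds-of-pC scale) and per event.

## Group statistics

`wilcoxon_one_tailed()` and `mann_whitney_one_tailed()` are exact by
enumeration wherever that is feasible: the signed-rank null from
`psignrank` (no ties, n ≤ 25) or full 2ⁿ sign enumeration of mid-ranks
(ties, n ≤ 20); the rank-sum null from `pwilcox` or full `choose(n+m, n)`
assignment enumeration with mid-ranks. With ties the U distribution is not
symmetric, so the "greater" tail is computed as `P(U ≥ u)` directly rather
than by reflection. Beyond those sizes a normal approximation with
continuity and tie corrections takes over; the method used is always
reported. Exactness is the point: n paired recordings all moving in the
tested direction give exactly 2⁻ⁿ — 0.0313, 0.0156, 0.0039 at n = 5, 6, 8 —
which are precisely the values small paired slice experiments print. Zero
differences are dropped (standard signed-rank convention). Time-courses are
binned at 1 min and normalised to the mean of the five leading control bins
(`normalize_timecourse()`, idempotent by construction); percent changes are
computed per recording and averaged, with the pooled ratio-of-means reported
alongside, since the two differ under between-slice scale jitter.

## The synthetic generator

`gen_lfp()` builds the gamma component as a complex
Ornstein–Uhlenbeck-modulated carrier,
`γ(t) = σ_γ √2 · Re(z(t) e^{i2πf₀t})`, with `z` a unit-variance complex OU
process of correlation time `envelope_tau_s`. Its autocorrelation is exactly
`σ_γ² e^{−τ/τ_env} cos(2πf₀τ)` — the damped-cosine family the rhythmicity
module is tested against — and its 20–80 Hz integrated power is `σ_γ²`
within 10%, giving both Cr and power closed-form handles. A `1/f^β`
Gaussian background (β = 1 by default) is added. Defaults: 10 kHz, f₀ =
35 Hz, σ_γ = 30 µV (interface-chamber power scale), background 15 µV.

Two realism limits are worth stating plainly. First, the narrowband envelope
(τ_env = 0.5 s) required to keep the gamma power inside the 20–80 Hz band
makes the synthetic oscillation far more regular (control Cr ≈ 0.98) than
biological slice gamma (control Cr ≈ 0.5); τ_env ≈ 15 ms reproduces
slice-like Cr but then ~25% of the generated gamma power leaks out of band.
Since Cr enters the analyses only through its *differences* between
conditions, we kept the power contract and treat `envelope_tau_s` as the
user's rhythmicity dial. Second, the PSC generator does not place two events
within 5 ms of each other — the detector's merge window — because such pairs
are unresolvable in principle; at a nominal 20 Hz the realised rate is
~18 Hz, and detector scoring is always against the generator's own truth
list. Passing tests therefore demonstrate estimator correctness under the
modelled statistical structure (narrowband gamma + 1/f noise, von Mises
phase locking, difference-of-exponential events with Gaussian noise), not
robustness to artefacts real recordings add: line noise, electrode drift,
population spikes, bursting, or overlapping compound events.

`gen_spikes_locked()` draws an inhomogeneous Poisson train with intensity
`λ(t) = r₀ · e^{κ cos(φ(t) − μ)} / I₀(κ)` by thinning, using the package's
own phase estimator for φ, so spike phases converge to von Mises(μ, κ) and
the mean rate to r₀ (κ = 0 gives an unlocked homogeneous train, used for
null calibration). `gen_experiment()` assembles paired control/treatment
datasets: per recording a lognormal scale jitter (CV 0.3 — a declared
stand-in, since only summary statistics of between-slice variability are
available) applied to both epochs, and treatment parameters scaled by the
condition's effect ratios. The default ratios are the acute whole-cell
anchors: gamma power ×0.60, half-width ×1.30 (implemented as κ → κ/1.30²,
since FWHM ≈ 2.355/√κ for concentrated von Mises), firing rate ×0.53 (the
mean per-cell reduction; the ratio of group means, 0.45, is the other
defensible reading), PSC amplitude ×0.77. The rescue condition (`abeta_cp`)
sets all ratios to 1; the antagonist condition (`abeta_cp_cz`) restores the
degradation ratios. A cell-attached-style preset with rate ratio > 1 can be
expressed by passing a custom `condition_effects()`.

## Pipelines, exclusions, determinism

`run_protocol()` orchestrates three protocols — `lfp_power_cr`,
`spike_phase`, `psc` — over any paired dataset, computing per-recording
metrics on both epochs, mean ± SEM summaries, per-recording percent changes,
and the one-tailed matched-pairs test per metric (boolean flags and
per-recording p-values are carried in the table but not group-tested).
Recordings that cannot be analysed — missing channel, fewer than 5 spikes,
Rayleigh gate failure — are excluded with a logged reason. Reports carry a
schema version and serialise deterministically (`report_to_json()`: no
timestamps, fixed ordering, full-precision numbers), so identical data and
configuration give byte-identical output; all generator randomness is seeded
explicitly.

## Numerical choices and problem sizes

Tolerances used in validation: Parseval and sine-power calibration at 5%;
generator power recovery at 10%; half-width recovery at 7% over 100 seeds
per σ; Rayleigh type-I error 0.05 ± 0.01 over 10⁴ null draws; PSC
recall/precision ≥ 0.95 at SNR 5 with ±2 ms onset matching; exact-test
p-values at 10⁻¹² against enumeration. The test suite and the acceptance
script run the synthetic experiments at 10 recordings per condition with 60-s
LFP epochs (150 s for spike-phase protocols, ~300 spikes per epoch at 2 Hz),
sizes chosen so each paired contrast is decided by the injected effects
rather than estimator noise while the whole suite stays desk-scale; the
rescue time-course check averages six recordings at a 5-min measurement
cadence, mirroring how group time-course figures are built. Degenerate inputs
are decided, not crashed on: zero-variance traces error in
`autocorrelogram()` but flat autocorrelograms yield Cr = 0; empty spike
trains report 0 Hz; uniform phase samples are excluded by the gate with the
exclusion logged.
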