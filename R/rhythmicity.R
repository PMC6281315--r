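#' Band-pass pre-filter (RC high-pass + Gaussian low-pass)
#'
#' High-pass: single-pole RC response with its -3 dB point at `f_hp`, applied
#' forward-backward so the output is zero-phase (the cascade magnitude is the
#' squared single-pass magnitude). Low-pass: symmetric Gaussian FIR kernel
#' whose -3 dB point sits at `f_lp`; being symmetric it is zero-phase in a
#' single pass. DC is removed exactly (the high-pass has a zero at 0 Hz).
#' Zero-phase filtering matters here: rhythmicity and spike-phase metrics must
#' not be biased by filter delay.
#'
#' @param rec A `gk_recording` (any channel kind; typically LFP).
#' @param f_hp High-pass -3 dB frequency, Hz.
#' @param f_lp Low-pass -3 dB frequency, Hz.
#' @return A `gk_recording` with filtered samples.
#' @export
bandpass <- function(rec, f_hp = 15, f_lp = 60) {
  stopifnot(inherits(rec, "gk_recording"))
  rate <- rec$rate_hz
  if (!(0 < f_hp && f_hp < f_lp && f_lp < rate / 2))
    stop("require 0 < f_hp < f_lp < rate/2")
  hp <- signal::butter(1, f_hp / (rate / 2), type = "high")
  y <- signal::filtfilt(hp, rec$samples - mean(rec$samples))
  y <- gaussian_lowpass(y, f_lp, rate)
  out <- rec
  out$samples <- y
  out
}

# Symmetric Gaussian FIR low-pass, -3 dB at f_lp. Amplitude response of a
# continuous Gaussian kernel of width sigma_t is exp(-2 pi^2 f^2 sigma_t^2);
# |H(f_lp)|^2 = 1/2 fixes sigma_t = sqrt(ln 2)/(2 pi f_lp). Edges handled by
# reflection padding; convolution via FFT.
gaussian_lowpass <- function(x, f_lp, rate) {
  sigma_t <- sqrt(log(2)) / (2 * pi * f_lp)
  sigma_n <- sigma_t * rate
  half <- max(1L, ceiling(4 * sigma_n))
  k <- exp(-((-half):half)^2 / (2 * sigma_n^2))
  k <- k / sum(k)
  n <- length(x)
  pad <- min(half, n - 1L)
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  m <- length(xp) + length(k) - 1L
  nf <- stats::nextn(m)
  conv <- Re(stats::fft(stats::fft(c(xp, numeric(nf - length(xp)))) *
                        stats::fft(c(k, numeric(nf - length(k)))), inverse = TRUE)) / nf
  conv[(pad + half + 1L):(pad + half + n)]
}

#' Analytic amplitude response of the band-pass cascade
#'
#' Magnitude of [bandpass()] at frequency `f`: squared single-pass RC
#' high-pass response (forward-backward application) times the Gaussian
#' low-pass response. Useful as a closed-form reference when checking the
#' filter against measured sine attenuation.
#'
#' @param f Frequency (Hz), vectorised.
#' @param f_hp,f_lp The band's -3 dB points, Hz.
#' @return Amplitude ratio(s) in `[0, 1]`.
#' @export
bandpass_response <- function(f, f_hp = 15, f_lp = 60) {
  r <- f / f_hp
  hp1 <- r / sqrt(1 + r^2)               # single-pass RC high-pass magnitude
  sigma_t <- sqrt(log(2)) / (2 * pi * f_lp)
  lp <- exp(-2 * pi^2 * f^2 * sigma_t^2) # Gaussian FIR magnitude
  hp1^2 * lp
}

#' Autocorrelogram of a filtered LFP segment
#'
#' Biased autocovariance normalised by the lag-0 autocovariance, computed over
#' lags `[-max_lag_ms, +max_lag_ms]` (100 ms by default). The trace is
#' mean-subtracted internally. `r01 = (r + 1)/2` is the affine rescale of the
#' correlation onto `[0, 1]` used for the coefficient of rhythmicity.
#'
#' @param rec A `gk_recording`, typically band-passed 15-60 Hz.
#' @param max_lag_ms Maximal lag, ms.
#' @return A `gk_acg` with `lags_ms`, `r`, `r01` and `rate_hz`.
#' @export
autocorrelogram <- function(rec, max_lag_ms = 100) {
  stopifnot(inherits(rec, "gk_recording"))
  x <- rec$samples - mean(rec$samples)
  n <- length(x)
  if (n < rec$rate_hz) stop("segment must be at least 1 s long")
  v <- sum(x^2)
  if (v <= 0) stop("degenerate trace: zero variance")
  max_lag <- round(max_lag_ms / 1000 * rec$rate_hz)
  # biased autocovariance via FFT (zero padding prevents circular wrap)
  nf <- stats::nextn(n + max_lag)
  X <- stats::fft(c(x, numeric(nf - n)))
  ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:(max_lag + 1L)] / nf
  r_pos <- ac / ac[1]
  r <- c(rev(r_pos[-1]), r_pos)
  lags_ms <- ((-max_lag):max_lag) / rec$rate_hz * 1000
  structure(list(lags_ms = lags_ms, r = r, r01 = (r + 1) / 2, rate_hz = rec$rate_hz),
            class = "gk_acg")
}

#' Build an autocorrelogram object from a known correlation function
#'
#' Intended for validation: evaluate a closed-form autocorrelation (for
#' instance a damped cosine) on a lag grid and wrap it as a `gk_acg` so the
#' peak/trough extraction can be exercised against analytic values.
#'
#' @param r_fun Function of lag in *seconds* returning the correlation.
#' @param rate_hz Lag grid resolution (samples per second).
#' @param max_lag_ms Maximal lag, ms.
#' @return A `gk_acg`.
#' @export
acg_from_function <- function(r_fun, rate_hz = 10000, max_lag_ms = 100) {
  max_lag <- round(max_lag_ms / 1000 * rate_hz)
  lags_s <- (0:max_lag) / rate_hz
  r_pos <- r_fun(lags_s)
  r <- c(rev(r_pos[-1]), r_pos)
  structure(list(lags_ms = ((-max_lag):max_lag) / rate_hz * 1000,
                 r = r, r01 = (r + 1) / 2, rate_hz = rate_hz),
            class = "gk_acg")
}

#' @export
print.gk_acg <- function(x, ...) {
  cat(sprintf("<gk_acg> lags [%g, %g] ms at %.3g ms resolution\n",
              min(x$lags_ms), max(x$lags_ms), 1000 / x$rate_hz))
  invisible(x)
}

#' Coefficient of rhythmicity
#'
#' From the rescaled autocorrelogram `r01`, the first local minimum at a
#' positive lag gives the trough value `beta` and the first local maximum
#' beyond it gives the second-peak value `alpha` (the lag-0 peak counting as
#' the first). `Cr = (alpha - beta)/(alpha + beta)`, clipped to `[0, 1]`.
#' Extrema are *located* on a 1-ms boxcar-smoothed copy to suppress
#' sample-level jitter (ties broken toward the smaller lag), but `alpha` and
#' `beta` are read from the raw `r01` at the located lags so smoothing cannot
#' bias the values. The peak lag implies an oscillation frequency
#' `1000/peak_lag_ms` Hz.
#'
#' @param acg A `gk_acg`.
#' @param rhythmic_threshold Cr at or above which the segment is flagged
#'   rhythmic (default 0.01).
#' @return A `gk_cr` with `alpha`, `beta`, `cr`, `trough_lag_ms`,
#'   `peak_lag_ms`, `implied_freq_hz`, `rhythmic`.
#' @export
coefficient_of_rhythmicity <- function(acg, rhythmic_threshold = 0.01) {
  stopifnot(inherits(acg, "gk_acg"))
  pos <- acg$lags_ms > 0
  lags <- acg$lags_ms[pos]
  y_raw <- acg$r01[pos]
  win <- max(1L, round(acg$rate_hz / 1000))
  if (win %% 2L == 0L) win <- win + 1L # odd: symmetric, no half-sample shift
  y <- smooth_boxcar(y_raw, win)
  trough_i <- first_local_extremum(y, which = "min", from = 1L)
  degenerate <- list(alpha = NA_real_, beta = NA_real_, cr = 0,
                     trough_lag_ms = NA_real_, peak_lag_ms = NA_real_,
                     implied_freq_hz = NA_real_, rhythmic = FALSE)
  if (is.na(trough_i)) return(structure(degenerate, class = "gk_cr"))
  peak_i <- first_local_extremum(y, which = "max", from = trough_i + 1L)
  if (is.na(peak_i)) return(structure(degenerate, class = "gk_cr"))
  alpha <- y_raw[peak_i]
  beta <- y_raw[trough_i]
  cr <- (alpha - beta) / (alpha + beta)
  cr <- min(1, max(0, cr))
  structure(list(alpha = alpha, beta = beta, cr = cr,
                 trough_lag_ms = lags[trough_i], peak_lag_ms = lags[peak_i],
                 implied_freq_hz = 1000 / lags[peak_i],
                 rhythmic = cr >= rhythmic_threshold),
            class = "gk_cr")
}

#' @export
print.gk_cr <- function(x, ...) {
  cat(sprintf("<gk_cr> Cr = %.3f (alpha %.3f @ %.2f ms, beta %.3f @ %.2f ms) implied %.1f Hz%s\n",
              x$cr, x$alpha, x$peak_lag_ms, x$beta, x$trough_lag_ms,
              x$implied_freq_hz, if (isTRUE(x$rhythmic)) "" else " [not rhythmic]"))
  invisible(x)
}

#' Cross-check the autocorrelogram frequency against the power spectrum
#'
#' @param cr_result A `gk_cr` from [coefficient_of_rhythmicity()].
#' @param spectrum A `gk_spectrum` of the same segment.
#' @param tol_hz Agreement tolerance, Hz (default 5).
#' @param f_lo,f_hi Band searched for the spectral peak.
#' @return TRUE iff the implied frequency and spectral peak agree within
#'   `tol_hz`; FALSE (never an error) otherwise, including non-rhythmic input.
#' @export
confirm_frequency <- function(cr_result, spectrum, tol_hz = 5, f_lo = 20, f_hi = 80) {
  if (!isTRUE(cr_result$rhythmic) || is.na(cr_result$implied_freq_hz)) return(FALSE)
  abs(cr_result$implied_freq_hz - peak_frequency(spectrum, f_lo, f_hi)) <= tol_hz
}

smooth_boxcar <- function(y, win) {
  if (win <= 1L) return(y)
  k <- rep(1 / win, win)
  n <- length(y)
  pad <- win %/% 2L
  yp <- c(rep(y[1], pad), y, rep(y[n], win - pad - 1L))
  as.numeric(stats::filter(yp, k, sides = 1))[win:(win + n - 1L)]
}

# first strict local extremum scanning from index `from`; flat ties resolve to
# the smallest lag by the >=/<= asymmetry of the comparison
first_local_extremum <- function(y, which = c("min", "max"), from = 1L) {
  which <- match.arg(which)
  n <- length(y)
  if (n < 3L || from > n - 1L) return(NA_integer_)
  for (i in max(2L, from):(n - 1L)) {
    if (which == "min") {
      if (y[i] < y[i - 1L] && y[i] <= y[i + 1L]) return(i)
    } else {
      if (y[i] > y[i - 1L] && y[i] >= y[i + 1L]) return(i)
    }
  }
  NA_integer_
}
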