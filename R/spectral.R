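#' Welch power spectrum of an LFP segment
#'
#' Averaged modified periodograms: the segment is cut into half-overlapping
#' windows of `seg_len` samples (8192 by default, ~1.22 Hz resolution at
#' 10 kHz), each window Hann-tapered, and periodograms are averaged with the
#' taper power normalised out. The convention is *per-bin total power* in V²:
#' summing all bins recovers the variance of the trace (Parseval), so a band
#' sum is directly an integrated band power.
#'
#' @param segment A `gk_recording` of kind `"lfp"` (typically a 60-s segment).
#' @param seg_len FFT window length in samples (default 8192).
#' @param demean Subtract the segment mean before analysis (default TRUE).
#' @return A `gk_spectrum` with fields `freqs_hz`, `power` (V² per bin),
#'   `df_hz`, `seg_len_samples`, `n_segments_averaged`, `rate_hz`.
#' @export
power_spectrum <- function(segment, seg_len = 8192L, demean = TRUE) {
  stopifnot(inherits(segment, "gk_recording"))
  if (segment$channel_kind != "lfp")
    stop("power_spectrum expects an LFP recording")
  x <- segment$samples
  n <- length(x)
  if (n < seg_len)
    stop(sprintf("segment (%d samples) shorter than one %d-sample window", n, seg_len))
  if (demean) x <- x - mean(x)
  rate <- segment$rate_hz
  hop <- seg_len %/% 2L
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  w <- hann_window(seg_len)
  wss <- sum(w^2)
  nbin <- seg_len %/% 2L + 1L
  acc <- numeric(nbin)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    X <- stats::fft(seg)
    # two-sided per-bin power |X_k|^2 / (N * sum(w^2)); fold onto one side
    p2 <- (Mod(X)^2) / (seg_len * wss)
    p1 <- p2[1:nbin]
    if (seg_len %% 2L == 0L) {
      p1[2:(nbin - 1L)] <- p1[2:(nbin - 1L)] + p2[seg_len:(nbin + 1L)]
    } else {
      p1[2:nbin] <- p1[2:nbin] + p2[seg_len:(nbin + 1L)]
    }
    acc <- acc + p1
  }
  structure(
    list(freqs_hz = (0:(nbin - 1L)) * rate / seg_len,
         power = acc / length(starts),
         df_hz = rate / seg_len,
         seg_len_samples = as.integer(seg_len),
         n_segments_averaged = length(starts),
         rate_hz = rate),
    class = "gk_spectrum")
}

#' @export
print.gk_spectrum <- function(x, ...) {
  cat(sprintf("<gk_spectrum> %d bins, df = %.4g Hz, %d windows of %d samples; total power %.4g V^2\n",
              length(x$freqs_hz), x$df_hz, x$n_segments_averaged,
              x$seg_len_samples, sum(x$power)))
  invisible(x)
}

#' Spectral power density view (V²/Hz)
#' @param spectrum A `gk_spectrum`.
#' @return Numeric vector, per-bin power divided by the bin width.
#' @export
power_density <- function(spectrum) spectrum$power / spectrum$df_hz

#' Integrated band power
#'
#' Sum of per-bin power for bins whose centre lies in `[f_lo, f_hi]`. With the
#' defaults this is the 20-80 Hz integrated gamma power in V².
#'
#' @param spectrum A `gk_spectrum`.
#' @param f_lo,f_hi Band edges in Hz (`f_lo < f_hi <= rate/2`).
#' @return Integrated power (V²), non-negative.
#' @export
integrated_power <- function(spectrum, f_lo = 20, f_hi = 80) {
  if (!(f_lo < f_hi)) stop("f_lo must be < f_hi")
  if (f_hi > max(spectrum$freqs_hz) + spectrum$df_hz / 2)
    stop("band extends beyond the spectrum's support")
  keep <- spectrum$freqs_hz >= f_lo & spectrum$freqs_hz <= f_hi
  sum(spectrum$power[keep])
}

#' Peak frequency within a band
#' @param spectrum A `gk_spectrum`.
#' @param f_lo,f_hi Band in Hz.
#' @return Frequency (Hz) of the maximal bin within the band.
#' @export
peak_frequency <- function(spectrum, f_lo = 20, f_hi = 80) {
  keep <- which(spectrum$freqs_hz >= f_lo & spectrum$freqs_hz <= f_hi)
  if (!length(keep)) stop("band outside spectrum support")
  spectrum$freqs_hz[keep[which.max(spectrum$power[keep])]]
}

#' Spectrogram of an LFP recording
#'
#' Successive windows `[t, t + window_s)` advanced by `step_s`; each column is
#' the Welch spectrum of its window restricted to `band`. The FFT length
#' defaults to the full window so each column is a single Hann periodogram.
#'
#' @param rec A `gk_recording` of kind `"lfp"`.
#' @param window_s Window length, seconds (>= 0.2).
#' @param step_s Step between window starts, seconds (<= window_s).
#' @param band Length-2 numeric band in Hz to retain (default `c(0, rate/2)`).
#' @param seg_len FFT length per window; defaults to the window length.
#' @return A `gk_spectrogram` with `times_s` (window starts), `freqs_hz`, and
#'   a `power` matrix (freq x time, V² per bin).
#' @export
spectrogram <- function(rec, window_s, step_s, band = NULL, seg_len = NULL) {
  stopifnot(inherits(rec, "gk_recording"))
  if (window_s < 0.2) stop("window_s must be >= 0.2 s")
  if (step_s > window_s) stop("step_s must be <= window_s")
  dur <- rec_duration(rec)
  if (dur < window_s) stop("recording shorter than one window")
  if (is.null(seg_len)) seg_len <- round(window_s * rec$rate_hz)
  if (is.null(band)) band <- c(0, rec$rate_hz / 2)
  starts <- seq(0, dur - window_s + 1e-9, by = step_s)
  cols <- lapply(starts, function(t0) {
    sp <- power_spectrum(rec_segment(rec, t0, window_s), seg_len = seg_len)
    keep <- sp$freqs_hz >= band[1] & sp$freqs_hz <= band[2]
    list(f = sp$freqs_hz[keep], p = sp$power[keep])
  })
  structure(
    list(times_s = starts, freqs_hz = cols[[1]]$f,
         power = vapply(cols, `[[`, numeric(length(cols[[1]]$f)), "p")),
    class = "gk_spectrogram")
}

#' Band power per spectrogram column
#' @param sg A `gk_spectrogram`.
#' @param f_lo,f_hi Band in Hz.
#' @return Numeric vector, one integrated band power per column.
#' @export
spectrogram_band_power <- function(sg, f_lo = 20, f_hi = 80) {
  keep <- sg$freqs_hz >= f_lo & sg$freqs_hz <= f_hi
  colSums(sg$power[keep, , drop = FALSE])
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
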