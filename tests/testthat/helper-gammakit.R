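# shared fixtures and independent oracles, built in code at test time

# pure sine recording (volts) at the given amplitude/frequency
sine_rec <- function(freq_hz, amp_v = 20e-6, dur_s = 60, rate = 10000,
                     kind = "lfp", phase = 0) {
  t <- (0:(round(dur_s * rate) - 1L)) / rate
  recording(amp_v * sin(2 * pi * freq_hz * t + phase), rate, kind)
}

cosine_rec <- function(freq_hz, amp_v = 20e-6, dur_s = 60, rate = 10000) {
  t <- (0:(round(dur_s * rate) - 1L)) / rate
  recording(amp_v * cos(2 * pi * freq_hz * t), rate, "lfp")
}

# wrapped-normal sample of circular angles
rwrappednorm <- function(n, mu, sigma) (stats::rnorm(n, mu, sigma)) %% (2 * pi)

# --- brute-force oracles for the exact tests --------------------------------

# one-tailed signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(before, after, direction = "less") {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  w_obs <- if (direction == "less") w_pos else sum(rk) - w_pos
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% rk)
  mean(w_all <= w_obs + 1e-9)
}

# one-tailed Mann-Whitney p by enumerating all C(n+m, n) group assignments,
# with U computed directly from the values (ties count one half)
oracle_mann_whitney_p <- function(x, y, direction = "less") {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  n <- length(x)
  pooled <- c(x, y)
  u_obs <- if (direction == "less") u_of(x, y) else u_of(y, x)
  combs <- utils::combn(length(pooled), n)
  u_all <- apply(combs, 2, function(ix) {
    if (direction == "less") u_of(pooled[ix], pooled[-ix]) else u_of(pooled[-ix], pooled[ix])
  })
  mean(u_all <= u_obs + 1e-9)
}

# analytic extrema of the damped-cosine autocorrelation
# r(tau) = exp(-tau/tau_d) * cos(2*pi*f*tau), rescaled to r01 = (r+1)/2:
# located by 1-D optimisation of the closed form (independent of the
# sample-grid extraction under test)
oracle_damped_cosine_extrema <- function(tau_d_s, f_hz = 40) {
  r01 <- function(tau) (exp(-tau / tau_d_s) * cos(2 * pi * f_hz * tau) + 1) / 2
  period <- 1 / f_hz
  tr <- stats::optimize(r01, c(1e-6, period), maximum = FALSE, tol = 1e-12)
  pk <- stats::optimize(r01, c(tr$minimum, 1.5 * period), maximum = TRUE, tol = 1e-12)
  alpha <- pk$objective
  beta <- tr$objective
  list(alpha = alpha, beta = beta, cr = (alpha - beta) / (alpha + beta),
       trough_lag_ms = tr$minimum * 1000, peak_lag_ms = pk$maximum * 1000)
}
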