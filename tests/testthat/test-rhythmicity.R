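test_that("band-pass filter kills DC and matches its analytic cascade response", {
  rate <- 10000
  dc <- recording(rep(3e-5, 60000), rate, "lfp")
  expect_lt(max(abs(bandpass(dc, 15, 60)$samples)), 1e-6 * 3e-5)
  # passband and stopband sines against the closed-form transfer magnitude
  for (f in c(40, 25, 200)) {
    rec <- sine_rec(f, amp_v = 1e-5, dur_s = 10)
    out <- bandpass(rec, 15, 60)
    core <- 20000:80000 # away from edges
    ratio <- sd(out$samples[core]) / sd(rec$samples[core])
    expect_equal(ratio, bandpass_response(f, 15, 60), tolerance = 0.02)
  }
  expect_lt(bandpass_response(200, 15, 60), 0.1)
  expect_error(bandpass(dc, 60, 15), "f_hp")
})

test_that("autocorrelogram is symmetric, unit at lag 0, and cosine-faithful", {
  acg <- autocorrelogram(cosine_rec(40, dur_s = 10))
  n0 <- which(acg$lags_ms == 0)
  expect_equal(acg$r[n0], 1)
  expect_equal(acg$r, rev(acg$r)) # r(-tau) = r(tau) exactly
  expect_gte(acg$r[acg$lags_ms == 25], 0.99)   # one 40 Hz period
  expect_lte(acg$r[acg$lags_ms == 12.5], -0.99) # half period
  expect_true(all(abs(acg$r) <= 1 + 1e-9))
})

test_that("white-noise autocorrelation vanishes beyond short lags", {
  set.seed(3)
  acg <- autocorrelogram(recording(rnorm(600000) * 1e-5, 10000, "lfp"))
  expect_lt(max(abs(acg$r[abs(acg$lags_ms) >= 5])), 0.05)
  expect_error(autocorrelogram(recording(rep(1, 20000), 10000, "lfp")), "degenerate")
})

test_that("Cr follows its defining formula on constructed autocorrelograms", {
  # raised cosine r(tau) = m + a cos(2 pi 40 tau) puts the r01 second peak at
  # alpha = (m + a + 1)/2 and the first trough at beta = (m - a + 1)/2
  mk <- function(alpha, beta) {
    a <- alpha - beta; m <- alpha + beta - 1
    acg_from_function(function(tau)
      ifelse(tau == 0, 1, m + a * cos(2 * pi * 40 * tau)), rate_hz = 10000)
  }
  got <- coefficient_of_rhythmicity(mk(0.9, 0.1))
  expect_equal(got$alpha, 0.9, tolerance = 1e-6)
  expect_equal(got$beta, 0.1, tolerance = 1e-6)
  expect_equal(got$cr, 0.8, tolerance = 1e-6)
  expect_equal(coefficient_of_rhythmicity(mk(0.9, 0))$cr, 1, tolerance = 1e-9)
  expect_equal(coefficient_of_rhythmicity(mk(0.4, 0.2))$cr, (0.4 - 0.2) / 0.6,
               tolerance = 1e-6)
})

test_that("Cr extraction matches the damped-cosine closed form", {
  for (tau_d in c(0.025, 0.05, 0.1)) {
    acg <- acg_from_function(function(tau) exp(-tau / tau_d) * cos(2 * pi * 40 * tau))
    got <- coefficient_of_rhythmicity(acg)
    want <- oracle_damped_cosine_extrema(tau_d)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-3)
    expect_equal(got$beta, want$beta, tolerance = 1e-3)
    expect_equal(got$cr, want$cr, tolerance = 1e-3)
    expect_equal(got$implied_freq_hz, 40, tolerance = 0.1 * 40)
    expect_true(got$rhythmic)
  }
  # the spec case tau_d = 50 ms: Cr near 0.758, trough ~12.5 ms, peak ~25 ms
  got50 <- coefficient_of_rhythmicity(
    acg_from_function(function(tau) exp(-tau / 0.05) * cos(2 * pi * 40 * tau)))
  expect_equal(got50$cr, 0.758, tolerance = 0.005)
  expect_equal(got50$trough_lag_ms, 12.5, tolerance = 0.15)
  expect_equal(got50$peak_lag_ms, 25, tolerance = 0.5)
})

test_that("degenerate flat autocorrelograms yield Cr 0, not an error", {
  acg <- acg_from_function(function(tau) exp(-tau / 0.001)) # no oscillation
  got <- coefficient_of_rhythmicity(acg)
  expect_equal(got$cr, 0)
  expect_false(got$rhythmic)
})

test_that("the autocorrelogram frequency is confirmed by the spectral peak", {
  rec <- sine_rec(40)
  sp <- power_spectrum(rec)
  crr <- coefficient_of_rhythmicity(autocorrelogram(bandpass(rec, 15, 60)))
  expect_true(confirm_frequency(crr, sp))
  # disagreeing spectral peak -> FALSE at the default 5 Hz tolerance
  sp55 <- power_spectrum(sine_rec(55))
  expect_false(confirm_frequency(crr, sp55))
  # broadband noise is not rhythmic -> vacuously FALSE
  set.seed(11)
  noise <- recording(rnorm(600000) * 1e-5, 10000, "lfp")
  crn <- coefficient_of_rhythmicity(autocorrelogram(noise))
  expect_false(confirm_frequency(crn, power_spectrum(noise)))
})
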