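test_that("threshold spike detection recovers injected APs and honours refractoriness", {
  rate <- 10000
  v <- rep(-60, 30000) # mV
  onsets <- c(0.5, 0.9, 1.4, 2.0, 2.7)
  ap <- c(seq(-60, 0, length.out = 5), seq(0, -60, length.out = 25)) + 60 # 3 ms bump
  for (o in onsets) {
    i <- round(o * rate)
    v[i:(i + 29)] <- v[i:(i + 29)] + ap
  }
  st <- detect_spikes(recording(v, rate, "voltage"), threshold = -20)
  expect_length(st$times_s, 5)
  expect_true(all(abs(st$times_s - onsets) < 0.5e-3))
  # flat trace -> 0 spikes with a warning
  expect_warning(st0 <- detect_spikes(recording(rep(-60, 1000), rate, "voltage"), -20),
                 "threshold")
  expect_length(st0$times_s, 0)
  # two crossings 1 ms apart with 2 ms refractory -> one spike
  v2 <- rep(-60, 5000)
  v2[1000:1003] <- 0
  v2[1010:1013] <- 0
  st2 <- detect_spikes(recording(v2, rate, "voltage"), -20)
  expect_length(st2$times_s, 1)
})

test_that("instantaneous phase of a pure cosine follows its analytic wrap", {
  rate <- 10000
  t <- (0:99999) / rate
  ph <- instantaneous_phase(recording(cos(2 * pi * 40 * t), rate, "lfp"))
  core <- 6000:94000 # outside the 0.5 s trimmed margins
  want <- (2 * pi * 40 * t[core]) %% (2 * pi)
  err <- abs((ph$phase[core] - want + pi) %% (2 * pi) - pi)
  expect_lt(max(err), 0.01)
  # convention: peak -> 0, trough -> pi, quarter period -> pi/2
  i_peak <- round(2 * rate) + 1L               # t = 2 s, cos = +1
  i_trough <- round((2 + 0.0125) * rate) + 1L  # half a 40 Hz period later
  i_quarter <- round((2 + 0.00625) * rate) + 1L
  expect_lt(abs(ph$phase[i_peak]), 0.01)
  expect_equal(ph$phase[i_trough], pi, tolerance = 0.01)
  expect_equal(ph$phase[i_quarter], pi / 2, tolerance = 0.01)
  # margins are invalidated
  expect_true(all(is.na(ph$phase[1:4999])))
  expect_error(instantaneous_phase(recording(rnorm(10000), rate, "lfp")), "2 s")
})

test_that("maxima of the filtered LFP sit at phase 0 (convention lock)", {
  lfp <- gen_lfp(lfp_sim_config(dur_s = 20, seed = 21))
  ph <- instantaneous_phase(lfp)
  filt <- bandpass(lfp, 20, 60)$samples
  n <- length(filt)
  is_max <- filt > c(-Inf, filt[-n]) & filt >= c(filt[-1], -Inf)
  pk <- which(is_max)
  pk <- pk[pk > 10000 & pk < n - 10000]
  d <- abs((ph$phase[pk] + pi) %% (2 * pi) - pi) # circular distance to 0
  expect_lt(stats::median(d), 0.1)
  expect_lt(mean(d), 0.3)
})

test_that("spike phases are looked up at the nearest sample and gated by epoch", {
  rate <- 10000
  t <- (0:99999) / rate
  rec <- recording(cos(2 * pi * 40 * t), rate, "lfp")
  ph <- instantaneous_phase(rec)
  peaks <- seq(1, 9, by = 0.025)   # spike exactly at oscillation peaks
  got <- spike_phases(spike_train(peaks, epoch = c(0, 10)), ph)
  expect_true(all(abs((got + pi) %% (2 * pi) - pi) < 0.05))
  troughs <- peaks + 0.0125
  got_t <- spike_phases(spike_train(troughs, epoch = c(0, 13)), ph)
  expect_true(all(abs(got_t - pi) < 0.05))
  # spikes in the trimmed margin or outside the epoch are dropped and counted
  mixed <- spike_train(c(0.1, 2, 5, 12), epoch = c(0, 13))
  got_m <- spike_phases(mixed, ph)
  expect_length(got_m, 2)
  expect_equal(attr(got_m, "n_dropped"), 2)
})

test_that("Rayleigh statistics behave at the concentration extremes", {
  r1 <- rayleigh_test(rep(2.3, 100))
  expect_equal(r1$R, 1)
  expect_lt(r1$p, 1e-10)
  r0 <- rayleigh_test(rep(c(0, pi / 2, pi, 3 * pi / 2), 2))
  expect_equal(r0$R, 0, tolerance = 1e-12)
  expect_gt(r0$p, 0.9)
  expect_error(rayleigh_test(c(0, 1, 2, 3)), "too few")
})

test_that("the preferred phase is the circular mean", {
  expect_equal(preferred_phase(rep(4, 50)), 4)
  expect_equal(preferred_phase(c(0.7, -0.7, 0.7, -0.7)), 0, tolerance = 1e-12)
  set.seed(5)
  ph <- rwrappednorm(2000, 5.2, 0.8)
  expect_equal(preferred_phase(ph), 5.2, tolerance = 0.05)
  expect_error(preferred_phase(seq(0, 2 * pi, length.out = 100)[-1]), "no preferred")
})

test_that("the Gaussian half-width recovers 2.355 sigma and degenerates gracefully", {
  set.seed(17)
  for (sigma in c(0.5, 1.0)) {
    hw <- replicate(20, {
      d <- phase_distribution(rwrappednorm(2000, 5.2, sigma))
      halfwidth(d)$halfwidth_rad
    })
    expect_equal(mean(hw), 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.07)
  }
  # all mass in one bin: half-width bounded by one bin width
  d1 <- phase_distribution(rep(1.0, 500))
  expect_lte(halfwidth(d1)$halfwidth_rad, 2 * pi / 36 + 1e-9)
  # the Rayleigh gate blocks uniform distributions
  du <- phase_distribution(runif(500, 0, 2 * pi))
  expect_false(du$included)
  expect_error(halfwidth(du), "Rayleigh")
})

test_that("firing rate averages 1-min bins and matches a Poisson oracle", {
  st <- spike_train(seq(0.25, 60, by = 0.5), epoch = c(0, 60))
  expect_equal(firing_rate(st)$rate_hz, 2)
  expect_equal(firing_rate(spike_train(numeric(0), epoch = c(0, 60)))$rate_hz, 0)
  set.seed(23)
  times <- cumsum(rexp(900, rate = 2))
  times <- times[times < 300]
  stp <- spike_train(times, epoch = c(0, 300), refractory_s = 0)
  fr <- firing_rate(stp)
  expect_equal(nrow(fr$per_bin), 5)
  expect_equal(fr$rate_hz, 2, tolerance = 0.1)
  expect_error(firing_rate(st, window = c(1, 1)), "zero-length")
})
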