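make_event_trace <- function(onsets_s, amp_pA = 20, rate = 10000, dur_s = 10,
                             tau_rise_ms = 0.5, tau_decay_ms = 5) {
  x <- numeric(round(dur_s * rate))
  tk <- (0:(round(0.05 * rate) - 1L)) / rate
  kern <- exp(-tk / (tau_decay_ms / 1000)) - exp(-tk / (tau_rise_ms / 1000))
  kern <- kern / max(kern)
  for (o in onsets_s) {
    i0 <- round(o * rate) + 1L
    ii <- i0:min(length(x), i0 + length(kern) - 1L)
    x[ii] <- x[ii] - amp_pA * kern[seq_along(ii)]
  }
  recording(x, rate, "current")
}

test_that("noiseless injected events are recovered with faithful amplitudes", {
  onsets <- c(1, 3.5, 7)
  rec <- make_event_trace(onsets, amp_pA = 20)
  ev <- detect_psc(rec, "inward", 5)
  expect_equal(nrow(ev), 3)
  expect_true(all(abs(ev$onset_s - onsets) < 1e-3))
  expect_equal(as.numeric(ev$peak_amplitude_pA), rep(-20, 3), tolerance = 0.5 / 20)
  # flat trace -> no events
  expect_equal(nrow(detect_psc(recording(numeric(1e4), 10000, "current"), "inward", 5)), 0)
  # wrong polarity -> warning and empty
  expect_warning(ev_out <- detect_psc(rec, "outward", 5), "polarity")
  expect_equal(nrow(ev_out), 0)
})

test_that("detection on the noisy generator meets recall and precision 0.95", {
  sim <- gen_psc(rate_hz = 20, amp_mean_pA = 25, amp_sd = 5, noise_sigma_pA = 2,
                 dur_s = 60, seed = 4)
  ev <- detect_psc(sim$recording, "inward", 5)
  sc <- score_detection(ev, sim$truth$onset_s, tol_ms = 2)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
  expect_equal(mean(ev$peak_amplitude_pA), -25, tolerance = 0.05)
})

test_that("recall does not improve as noise grows (SNR 10, 5, 3)", {
  recalls <- vapply(c(2.5, 5, 8.3), function(ns) {
    sim <- gen_psc(noise_sigma_pA = ns, dur_s = 30, seed = 8)
    sc <- score_detection(detect_psc(sim$recording, "inward", 5), sim$truth$onset_s)
    sc$recall
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-9))
})

test_that("charge transfer integrates area in pC", {
  rate <- 10000
  # rectangular 10 pA x 10 ms pulse -> 0.1 pC
  x <- numeric(3 * rate)
  x[rate:(rate + 0.01 * rate)] <- -10
  rect <- recording(x, rate, "current")
  expect_equal(charge_transfer(rect, 1.0, "inward", smooth_lp_hz = 0), -0.1,
               tolerance = 0.02)
  # instantaneous-rise exponential, A = 20 pA, tau = 5 ms -> ~A tau = 0.1 pC
  expo <- make_event_trace(1.0, amp_pA = 20, dur_s = 3, tau_rise_ms = 0.01)
  ev <- detect_psc(expo, "inward", 5)
  expect_equal(as.numeric(ev$charge_pC), -0.1, tolerance = 0.03)
  # zero-amplitude "event": integrating a flat stretch gives ~0
  flat <- recording(numeric(3 * rate), rate, "current")
  expect_equal(charge_transfer(flat, 1.0, "inward"), 0, tolerance = 1e-9)
})

test_that("detection is translation invariant", {
  sim <- gen_psc(dur_s = 20, seed = 12)
  ev1 <- detect_psc(sim$recording, "inward", 5)
  k <- 1537L
  shifted <- recording(c(sim$recording$samples[(k + 1):length(sim$recording$samples)],
                         sim$recording$samples[1:k]),
                       sim$recording$rate_hz, "current")
  ev2 <- detect_psc(shifted, "inward", 5)
  t_shift <- k / sim$recording$rate_hz
  common1 <- ev1$onset_s[ev1$onset_s > t_shift + 0.3 &
                           ev1$onset_s < rec_duration(sim$recording) - 0.3]
  matched <- vapply(common1 - t_shift, function(t) min(abs(ev2$onset_s - t)), numeric(1))
  expect_lt(max(matched), 1e-6)
})

test_that("per-event charge is consistent with the trace integral over supports", {
  sim <- gen_psc(noise_sigma_pA = 0, dur_s = 60, seed = 30)
  rec <- sim$recording
  ev <- detect_psc(rec, "inward", 5)
  # independent integral of the rectified baseline-subtracted trace over each
  # detected support (baseline: the documented 500 ms running median)
  rate <- rec$rate_hz
  d <- -(rec$samples - stats::runmed(rec$samples, round(0.5 * rate) + 1L,
                                     endrule = "median"))
  per_event <- vapply(seq_len(nrow(ev)), function(e) {
    ii <- (round(ev$onset_s[e] * rate) + 1L):(round(ev$end_s[e] * rate) + 1L)
    seg <- d[ii]
    sum((seg[-1] + seg[-length(seg)]) / 2) / rate
  }, numeric(1))
  expect_equal(sum(-ev$charge_pC), sum(per_event), tolerance = 0.01)
})

test_that("event summaries follow their definitions in 1-min bins", {
  mk_events <- function(onsets, amps) {
    structure(data.frame(onset_s = onsets, peak_s = onsets + 0.001,
                         peak_amplitude_pA = amps, charge_pC = amps * 0.005),
              class = c("gk_events", "data.frame"), polarity = "inward",
              rate_hz = 10000, epoch = c(0, max(onsets) + 1))
  }
  ev <- mk_events(seq(0.025, 60, by = 0.05), rep(-25, 1200))
  sm <- summarize_events(ev, epoch = c(0, 60))
  expect_equal(sm$summary$frequency_hz, 20)
  expect_equal(sm$summary$mean_amplitude_pA, -25)
  expect_error(summarize_events(ev, epoch = c(0, 30)), "complete bin")
  # Poisson train: mean IEI matches the exponential oracle
  set.seed(9)
  times <- cumsum(rexp(9000, 20))
  times <- times[times < 300]
  smp <- summarize_events(mk_events(times, rep(-20, length(times))), epoch = c(0, 300))
  expect_equal(nrow(smp$per_bin), 5)
  expect_equal(smp$summary$mean_iei_s, 0.05, tolerance = 0.1)
  expect_equal(smp$summary$frequency_hz, 20, tolerance = 0.05)
})
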