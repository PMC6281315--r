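test_that("recording construction enforces its invariants", {
  expect_error(recording(numeric(0), 10000, "lfp"), "at least one sample")
  expect_error(recording(c(1, NA), 10000, "lfp"), "non-finite")
  expect_error(recording(1:10, -1, "lfp"), "positive")
  expect_error(recording(1:10, 10000, "lfp", t0_s = -1), "t0_s")
  rec <- recording(sin(1:100), 10000, "lfp")
  expect_s3_class(rec, "gk_recording")
  expect_equal(rec_duration(rec), 0.01)
})

test_that("segment extraction is half-open and returns round(dur * rate) samples", {
  rec <- recording(seq_len(10000), 1000, "lfp")
  seg <- rec_segment(rec, 1, 2.5)
  expect_length(seg$samples, 2500)
  expect_equal(seg$samples[1], 1001) # sample at t = 1 s included
  expect_equal(seg$t0_s, 1)
  # contiguous tiling without duplication
  a <- rec_segment(rec, 0, 5)$samples
  b <- rec_segment(rec, 5, 5)$samples
  expect_equal(c(a, b), rec$samples)
  expect_error(rec_segment(rec, 9, 2), "not fully inside")
  expect_error(rec_segment(rec, 0, 0), "dur_s")
})

test_that("CSV + sidecar round trip preserves samples, rate and units", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "rec.csv"); js <- file.path(dir, "rec.json")
  rec <- recording(rnorm(300) * 1e-5, 10000, "lfp", t0_s = 2, condition = "abeta")
  write_recording(rec, csv, js)
  back <- read_recording(csv, js)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$rate_hz, 10000)
  expect_equal(back$channel_kind, "lfp")
  expect_equal(back$condition, "abeta")
})

test_that("sidecar rate and unit mismatches are hard errors", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "rec.csv"); js <- file.path(dir, "rec.json")
  utils::write.csv(data.frame(time_s = c(0, 1e-4, 2e-4), value = c(0, 1, 0)),
                   csv, row.names = FALSE)
  jsonlite::write_json(list(rate_hz = 10000, units = "V", channel_kind = "lfp"),
                       js, auto_unbox = TRUE)
  expect_equal(read_recording(csv, js)$rate_hz, 10000) # consistent: accepted
  jsonlite::write_json(list(rate_hz = 20000, units = "V", channel_kind = "lfp"),
                       js, auto_unbox = TRUE)
  expect_error(read_recording(csv, js), "rate mismatch.*20000.*10000")
  jsonlite::write_json(list(rate_hz = 10000, units = "mV", channel_kind = "lfp"),
                       js, auto_unbox = TRUE)
  expect_error(read_recording(csv, js), "units mismatch")
  # non-uniform sampling
  utils::write.csv(data.frame(time_s = c(0, 1e-4, 5e-4), value = c(0, 1, 0)),
                   csv, row.names = FALSE)
  jsonlite::write_json(list(rate_hz = 10000, units = "V", channel_kind = "lfp"),
                       js, auto_unbox = TRUE)
  expect_error(read_recording(csv, js), "non-uniform")
})

test_that("results tables round-trip with order preserved and 1e-12 precision", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "results.csv")
  tab <- data.frame(metric = "gamma_power", segment = sprintf("s%04d", 1:1000),
                    condition = "control",
                    value = 2e-10 * exp(rnorm(1000)), units = "V2")
  write_results(tab, path)
  back <- read_results(path)
  expect_equal(nrow(back), 1000)
  expect_identical(back$segment, tab$segment) # order preserved
  expect_equal(back$value, tab$value, tolerance = 1e-12)
  # empty table -> header-only file
  write_results(tab[0, ], path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_results(path)), 0)
})

test_that("spike trains must be strictly increasing, in-epoch and refractory", {
  expect_error(spike_train(c(1, 1, 2), epoch = c(0, 3)), "strictly increasing")
  expect_error(spike_train(c(1, 2, 5), epoch = c(0, 3)), "outside epoch")
  expect_error(spike_train(c(1, 1.001), epoch = c(0, 2)), "refractory")
  st <- spike_train(c(0.5, 1, 2), epoch = c(0, 3))
  expect_length(st$times_s, 3)
})
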