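toneRec <- function(freq, fs = 5000, dur = 20, amp = 100) {
  EcgRecording(amp * sin(2 * pi * freq * (0:(dur * fs - 1)) / fs), fs)
}

interiorRms <- function(rec, skip = 2) {
  x <- ecgSamples(rec)
  fs <- samplingRate(rec)
  m <- seq(skip * fs, length(x) - skip * fs)
  sqrt(mean(x[m]^2))
}

test_that("powerline filter attenuates 50 Hz by at least 30 dB", {
  inp <- toneRec(50)
  out <- removePowerline(inp)
  att <- 20 * log10(interiorRms(inp) / interiorRms(out))
  expect_gte(att, 30)
})

test_that("powerline filter leaves the 5 Hz passband within 1 dB", {
  inp <- toneRec(5)
  out <- removePowerline(inp)
  att <- abs(20 * log10(interiorRms(inp) / interiorRms(out)))
  expect_lt(att, 1)
})

test_that("filters map zero input to zero output", {
  z <- EcgRecording(numeric(5000), 1000)
  expect_true(all(abs(ecgSamples(removePowerline(z))) < 1e-9))
  expect_true(all(abs(ecgSamples(removeBaseline(z))) < 1e-9))
})

test_that("baseline removal rejects DC and sub-0.5 Hz wander", {
  fs <- 1000
  tt <- (0:(40 * fs - 1)) / fs
  const <- EcgRecording(rep(100, length(tt)), fs)
  out <- removeBaseline(const)
  expect_lt(abs(mean(ecgSamples(out))), 1)
  wander <- EcgRecording(200 * sin(2 * pi * 0.1 * tt), fs)
  res <- removeBaseline(wander)
  expect_lt(interiorRms(res, 5) / interiorRms(wander, 5), 0.10)
})

test_that("baseline removal preserves R-peak amplitudes within 10%", {
  rr <- simulateRRSeries(30, seed = 12)
  sim <- simulateEcg(rr, samplingRate = 1000, powerlineAmp = 0,
                     baselineWanderAmp = 0, seed = 12)
  rec <- sim$recording
  out <- removeBaseline(rec)
  idx <- round(sim$truePeaks * 1000) + 1
  ampIn <- ecgSamples(rec)[idx]
  ampOut <- ecgSamples(out)[idx]
  expect_true(all(abs(ampOut - ampIn) / ampIn < 0.10))
})

test_that("resampling shortens by the rate ratio and is identity at rate", {
  rec <- EcgRecording(rnorm(50000), 5000)
  out <- resampleEcg(rec, 1000)
  expect_equal(length(out), 10000L)
  expect_equal(samplingRate(out), 1000)
  expect_identical(resampleEcg(rec, 5000), rec)
  expect_error(resampleEcg(rec, 10000), "upsampling")
})

test_that("a 10 Hz tone passes resampling with under 1% amplitude change", {
  inp <- toneRec(10, fs = 5000, dur = 20)
  out <- resampleEcg(inp, 1000)
  expect_lt(abs(interiorRms(out) / interiorRms(inp) - 1), 0.01)
})

test_that("zero-phase filtering shifts R peaks by at most 2 ms", {
  rr <- simulateRRSeries(60, seed = 13)
  sim <- simulateEcg(rr, samplingRate = 1000, powerlineAmp = 50,
                     baselineWanderAmp = 200, seed = 13)
  rec <- preprocessEcg(sim$recording, filterSpec(targetRate = 1000))
  pk <- detectRPeaks(rec)
  err <- vapply(peakTimes(pk), function(t) min(abs(sim$truePeaks - t)),
                numeric(1))
  expect_lt(median(err), 0.002)
})

test_that("filter-first and downsample-first orders agree on R peaks", {
  rr <- simulateRRSeries(120, seed = 14)
  sim <- simulateEcg(rr, samplingRate = 5000, powerlineAmp = 50,
                     baselineWanderAmp = 200, seed = 14)
  recall <- function(spec) {
    rec <- preprocessEcg(sim$recording, spec)
    pk <- detectRPeaks(rec)
    mean(vapply(sim$truePeaks,
                function(t) min(abs(peakTimes(pk) - t)) < 0.005, logical(1)))
  }
  r1 <- recall(filterSpec(downsampleFirst = FALSE))
  r2 <- recall(filterSpec(downsampleFirst = TRUE))
  expect_lt(abs(r1 - r2), 0.005)
})

test_that("filter specification guards its invariants", {
  expect_error(filterSpec(passbandEdge = 120), "below the stopband")
  expect_error(filterSpec(highpassCutoff = -1), "positive")
  lowRate <- EcgRecording(rnorm(500), 150)
  expect_error(removePowerline(lowRate), "stopband")
})
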