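mkSeries <- function(x) RRSeries(cumsum(c(0, x[-length(x)])) / 1000, x)

test_that("SDRR matches hand-computed sample standard deviations", {
  expect_equal(sdrr(mkSeries(c(800, 800, 800))), 0)
  expect_equal(sdrr(mkSeries(c(800, 900, 1000))), 100)
  expect_equal(sdrr(mkSeries(c(800, 900))), sqrt(5000))
  expect_error(sdrr(mkSeries(800)), "two retained")
})

test_that("RMSSD matches hand computation and respects deletion gaps", {
  expect_equal(rmssd(mkSeries(rep(900, 5))), 0)
  expect_equal(rmssd(mkSeries(c(800, 810, 790))), sqrt(250))
  gappy <- RRSeries(c(0, 0.8, 1.9, 2.8), c(800, 1100, 900, 910),
                    valid = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(rmssd(gappy), 10)
  lone <- RRSeries(c(0, 0.8, 1.9), c(800, 1100, 900),
                   valid = c(TRUE, FALSE, TRUE))
  expect_error(rmssd(lone), "no adjacent pair")
})

test_that("window grid follows the 6-min/30-s protocol", {
  expect_equal(nrow(buildWindowGrid(1800)), 49L)
  expect_equal(nrow(buildWindowGrid(360)), 1L)
  expect_error(buildWindowGrid(359), "shorter")
  g <- buildWindowGrid(1800)
  expect_true(all(diff(g$start) == 30))
  expect_true(all(g$end - g$start == 360))
})

test_that("windows over the 20% deletion budget are rejected", {
  x <- rep(800, 500)
  rr <- mkSeries(x)
  # invalidate ~25% of the first window's time
  nBad <- ceiling(0.25 * 360 / 0.8)
  valid <- rep(TRUE, length(x))
  valid[10 + seq_len(nBad)] <- FALSE
  rr2 <- RRSeries(rrOnsets(rr), rrIntervals(rr), valid = valid)
  g <- windowUsability(rr2, buildWindowGrid(duration(rr2)))
  expect_false(g$accepted[1])
  expect_true(any(g$accepted))
})

test_that("spline tachogram reproduces constants and sinusoid frequency", {
  rr <- mkSeries(rep(850, 600))
  tach <- interpolateRR(rr, c(0, 360))
  expect_true(all(abs(tach$rr - 850) < 1e-6))
  sine <- simulateRRSeries(400, meanRR = 1000, lfAmp = 0, hfAmp = 30,
                           respFreq = 0.25, broadbandSD = 0, seed = 41)
  tach <- interpolateRR(rejectArtifacts(sine), c(0, 360))
  spec <- Mod(fft(tach$rr - mean(tach$rr)))[2:(length(tach$rr) / 2)]
  fDom <- (which.max(spec)) * 4 / length(tach$rr)
  expect_equal(fDom, 0.25, tolerance = 0.01)
})

test_that("Welch band power recovers analytic sinusoid power", {
  fs <- 4
  tt <- (0:(360 * fs - 1)) / fs
  x <- 20 * sin(2 * pi * 0.25 * tt)
  psd <- welchPsd(x, fs)
  hf <- welchBandPower(psd, c(0.15, 0.4))
  lf <- welchBandPower(psd, c(0.04, 0.15))
  expect_lt(abs(hf - 200) / 200, 0.10)
  expect_lt(lf, 2)
  expect_equal(welchBandPower(welchPsd(numeric(1500), fs), c(0.15, 0.4)), 0)
  expect_error(welchBandPower(psd, c(0.5, 3)), "Nyquist")
})

test_that("Welch band powers satisfy Parseval on white noise", {
  set.seed(42)
  x <- rnorm(360 * 4, sd = 30)
  psd <- welchPsd(x, 4)
  total <- welchBandPower(psd, c(0, 2))
  expect_lt(abs(total - var(x)) / var(x), 0.10)
})

test_that("phase summary recovers generator ground truth", {
  rr <- simulateRRSeries(1200, meanRR = 900, lfAmp = 30, hfAmp = 25,
                         respFreq = 0.25, broadbandSD = 10, seed = 43)
  s <- phaseHrvSummary(rejectArtifacts(rr))
  expect_equal(s$hr, 60000 / 900, tolerance = 0.02)
  expect_equal(s$sdrr, analyticSDRR(900, 30, 0.1, 25, 0.25, 10),
               tolerance = 0.10)
  expect_equal(s$rmssd, analyticRMSSD(900, 30, 0.1, 25, 0.25, 10),
               tolerance = 0.10)
  # HF: sinusoid power plus the broadband share of the band
  expect_equal(s$hf, 25^2 / 2, tolerance = 0.25)
  expect_gt(s$lf, 30^2 / 2 * 0.5)
  expect_equal(s$resp_cpm, 15, tolerance = 0.07)
  expect_gt(s$n_windows_used, 20)
})

test_that("single accepted window equals the phase aggregate", {
  rr <- simulateRRSeries(360, seed = 44)
  cl <- rejectArtifacts(rr)
  s <- phaseHrvSummary(cl)
  expect_equal(s$n_windows_used, 1L)
  tach <- interpolateRR(cl, c(0, 360))
  psd <- welchPsd(tach$rr, 4)
  expect_equal(s$hf, welchBandPower(psd, c(0.15, 0.4)))
})

test_that("zero spectral power leaves the LF/HF ratio undefined", {
  rr <- mkSeries(rep(900, 500))
  s <- phaseHrvSummary(rejectArtifacts(rr))
  expect_equal(s$hf, 0)
  expect_true(is.na(s$lfhf))
})

test_that("RMSSD never exceeds sqrt(2) SDRR on stationary draws", {
  for (sd in 51:56) {
    rr <- simulateRRSeries(400, meanRR = 800 + 40 * (sd - 51),
                           seed = sd)
    cl <- rejectArtifacts(rr)
    expect_lte(rmssd(cl), sqrt(2) * sdrr(cl) * (1 + 1e-8))
  }
})

test_that("HF is stable under window phase offsets", {
  rr <- simulateRRSeries(800, meanRR = 1000, lfAmp = 0, hfAmp = 20,
                         respFreq = 0.25, broadbandSD = 5, seed = 57)
  cl <- rejectArtifacts(rr)
  hfAt <- function(start) {
    tach <- interpolateRR(cl, c(start, start + 360))
    welchBandPower(welchPsd(tach$rr, 4), c(0.15, 0.4))
  }
  vals <- vapply(c(0, 30, 60, 90, 120), hfAt, numeric(1))
  expect_lt(diff(range(vals)) / mean(vals), 0.2)
  expect_true(all(abs(vals - 200) / 200 < 0.15))
})

test_that("doubling the respiratory amplitude quadruples HF", {
  hfFor <- function(amp, seed) {
    rr <- simulateRRSeries(900, meanRR = 1000, lfAmp = 0, hfAmp = amp,
                           respFreq = 0.25, broadbandSD = 0, seed = seed)
    phaseHrvSummary(rejectArtifacts(rr))$hf
  }
  h1 <- hfFor(10, 58)
  h2 <- hfFor(20, 58)
  expect_equal(h2 / h1, 4, tolerance = 0.15)
})
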