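test_that("degenerate no-modulation config yields constant beats", {
  rr <- simulateRRSeries(60, meanRR = 1000, lfAmp = 0, hfAmp = 0,
                         broadbandSD = 0)
  expect_equal(length(rr), 60L)
  expect_true(all(rrIntervals(rr) == 1000))
  expect_equal(rrOnsets(rr), 0:59)
})

test_that("seeded generation is reproducible and invariants hold", {
  a <- simulateRRSeries(300, seed = 42)
  b <- simulateRRSeries(300, seed = 42)
  expect_identical(rrIntervals(a), rrIntervals(b))
  expect_identical(rrOnsets(a), rrOnsets(b))
  expect_true(all(diff(rrOnsets(a)) > 0))
  expect_true(all(rrIntervals(a) > 0))
})

test_that("invalid R-R configurations are rejected", {
  expect_error(simulateRRSeries(-5), "duration")
  expect_error(simulateRRSeries(60, meanRR = 100, lfAmp = 30, hfAmp = 30),
               "positive")
  expect_error(simulateRRSeries(60, respFreq = 0.5), "respFreq")
})

test_that("empirical SDRR matches the analytic composition of amplitudes", {
  rr <- simulateRRSeries(3600, meanRR = 900, lfAmp = 30, hfAmp = 25,
                         broadbandSD = 15, seed = 9)
  expected <- analyticSDRR(900, 30, 0.1, 25, 0.25, 15)
  expect_lt(abs(sd(rrIntervals(rr)) - expected) / expected, 0.10)
})

test_that("ECG synthesis returns one ground-truth peak per beat", {
  rr <- simulateRRSeries(30, seed = 5)
  sim <- simulateEcg(rr, samplingRate = 1000, seed = 5)
  expect_equal(length(sim$truePeaks), length(rr) + 1L)
  expect_s4_class(sim$recording, "EcgRecording")
  expect_equal(samplingRate(sim$recording), 1000)
})

test_that("ECG synthesis rejects impossible configurations", {
  rr <- simulateRRSeries(10, seed = 1)
  expect_error(simulateEcg(rr, samplingRate = 100), "250")
  empty <- RRSeries(numeric(), numeric())
  expect_error(simulateEcg(empty), "zero beats")
})

test_that("movement artifacts reduce the retained fraction", {
  rr <- simulateRRSeries(180, seed = 6)
  sim <- simulateEcg(rr, samplingRate = 1000, artifactRate = 3,
                     artifactAmp = 2000, seed = 6)
  rec <- preprocessEcg(sim$recording, filterSpec(targetRate = 1000))
  clean <- suppressWarnings(rejectArtifacts(rrFromPeaks(detectRPeaks(rec))))
  expect_lt(retainedFraction(clean), 1)
})

test_that("ground-truth effects shift the generative indices exactly", {
  p <- list(meanRR = 850, lfAmp = 30, lfFreq = 0.1, hfAmp = 25,
            respFreq = 0.25, broadbandSD = 15)
  eff <- data.frame(index = c("hr", "rmssd", "sdrr"),
                    condition = "taVNS",
                    phase = "stimulation",
                    delta = c(3, -5, -6))
  q <- hrvCrossover:::applyPhaseEffects(p, eff[1, ], "taVNS", "stimulation")
  expect_equal(60000 / q$meanRR, 60000 / p$meanRR + 3)
  q <- hrvCrossover:::applyPhaseEffects(p, eff[2, ], "taVNS", "stimulation")
  expect_equal(do.call(analyticRMSSD, q), do.call(analyticRMSSD, p) - 5,
               tolerance = 1e-8)
  q <- hrvCrossover:::applyPhaseEffects(p, eff[3, ], "taVNS", "stimulation")
  expect_equal(do.call(analyticSDRR, q), do.call(analyticSDRR, p) - 6,
               tolerance = 1e-8)
  # sham phases are untouched by a taVNS-only effect
  q <- hrvCrossover:::applyPhaseEffects(p, eff, "sham", "stimulation")
  expect_identical(q, p)
  q <- hrvCrossover:::applyPhaseEffects(p, eff, "taVNS", "baseline")
  expect_identical(q, p)
})

test_that("study design honours the crossover layout", {
  des <- studyDesign(nSubjects = 8, phaseDuration = 400, seed = 3)
  s <- des$sessions
  expect_equal(nrow(s), 8 * 4 * 3)
  for (sub in unique(s$subject)) {
    b <- s[s$subject == sub & s$phase == "baseline", ]
    expect_equal(sort(paste(b$condition, b$side)),
                 sort(c("taVNS left", "taVNS right",
                        "sham left", "sham right")))
    # side fixed across sessions 1-2 and across 3-4
    expect_equal(b$side[b$session == 1], b$side[b$session == 2])
    expect_equal(b$side[b$session == 3], b$side[b$session == 4])
  }
})

test_that("a one-subject study simulates but inference refuses it", {
  des <- studyDesign(nSubjects = 1, effects = NULL, phaseDuration = 400,
                     seed = 11)
  sim <- simulateStudy(des, seed = 11)
  expect_equal(length(sim$series), 12L)
  expect_error(runStudyAnalysis(sim, nResamples = 1000, seed = 1),
               "refused|fewer")
})

test_that("study simulation is reproducible under a root seed", {
  des <- studyDesign(nSubjects = 2, phaseDuration = 380, seed = 4)
  a <- simulateStudy(des, seed = 21)
  b <- simulateStudy(des, seed = 21)
  expect_identical(lapply(a$series, rrIntervals),
                   lapply(b$series, rrIntervals))
})
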