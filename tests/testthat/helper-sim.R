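# fixtures shared across test files; everything is generated in code

# a small standard synthetic ECG suite: recordings with powerline + wander
makeEcgSuite <- function(nRec = 3, duration = 120, samplingRate = 5000,
                         artifactRate = 0) {
  lapply(seq_len(nRec), function(i) {
    rr <- simulateRRSeries(duration, seed = 100 + i)
    simulateEcg(rr, samplingRate = samplingRate, powerlineAmp = 50,
                baselineWanderAmp = 200, artifactRate = artifactRate,
                seed = 100 + i)
  })
}

# match detected peaks to truth within tol seconds
peakScores <- function(detected, truth, tol = 0.005) {
  errDet <- vapply(detected, function(t) min(abs(truth - t)), numeric(1))
  hit <- vapply(truth, function(t) min(abs(detected - t)) < tol, logical(1))
  list(recall = mean(hit), precision = mean(errDet < tol),
       medianErrMs = 1000 * stats::median(errDet))
}

# write a minimal BrainVision triplet (independent of the package writer)
writeBrainVisionFixture <- function(dir, x, samplingRate,
                                    resolution = 0.5) {
  base <- file.path(dir, "fix")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "DataFile=fix.eeg",
    "MarkerFile=fix.vmrk",
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    "NumberOfChannels=1",
    sprintf("SamplingInterval=%.10g", 1e6 / samplingRate),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch1=ECG,,%g,µV", resolution)
  ), paste0(base, ".vhdr"))
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", "DataFile=fix.eeg"), paste0(base, ".vmrk"))
  con <- file(paste0(base, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x / resolution), con, size = 4L, endian = "little")
  paste0(base, ".vhdr")
}

# independent step-up FDR oracle
bhStepUpOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# independent Simpson-rule quadrature for the JZS Bayes factor
jzsSimpsonOracle <- function(t, n, rscale = 0.5, lim = 20, nGrid = 40001) {
  d <- seq(-lim, lim, length.out = nGrid)
  h <- d[2] - d[1]
  f <- suppressWarnings(stats::dt(t, df = n - 1, ncp = d * sqrt(n))) *
    stats::dcauchy(d, 0, rscale)
  w <- rep(c(2, 4), length.out = nGrid)
  w[1] <- w[nGrid] <- 1
  alt <- sum(w * f) * h / 3
  alt / stats::dt(t, df = n - 1)
}
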