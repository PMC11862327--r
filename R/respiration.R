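# dominant-peak respiration estimate from one window's tachogram PSD
respFromPsd <- function(psd, respBand = c(0.12, 0.5), minRatio = 5,
                        plausible = c(6, 30)) {
  sel <- psd$freq >= respBand[1] & psd$freq < respBand[2]
  f <- psd$freq[sel]
  p <- psd$psd[sel]
  if (!length(p) || max(p) <= 0) {
    return(list(rate = NA_real_, reliable = FALSE))
  }
  i <- which.max(p)
  floorLevel <- median(p)
  rate <- 60 * f[i]
  reliable <- (floorLevel <= 0 || p[i] / floorLevel >= minRatio) &&
    rate >= plausible[1] && rate <= plausible[2]
  list(rate = rate, reliable = isTRUE(reliable))
}

#' Respiration rate from R-R interval variations
#'
#' Respiratory sinus arrhythmia imprints the breathing rhythm on the R-R
#' series, so the respiration rate is estimated per sliding window as the
#' dominant spectral peak of the interpolated tachogram within the
#' physiological band (default 0.12-0.5 Hz, placed just above the ~0.1 Hz
#' Mayer-wave peak so baroreflex oscillations are not mistaken for
#' breathing). A window's estimate is
#' flagged unreliable when the peak does not stand out from the spectral
#' floor (peak below `minRatio` times the in-band median PSD) or falls
#' outside 6-30 cycles/min.
#'
#' @param clean a [CleanRRSeries].
#' @param grid optional [buildWindowGrid()] data frame; built from the
#'   series duration when missing.
#' @param interpRate tachogram interpolation rate (Hz).
#' @param respBand search band in Hz (default `c(0.12, 0.5)`).
#' @param minRatio reliability threshold on peak-to-floor ratio (default 5).
#' @param maxRejected window rejection rule (default 0.2).
#' @return a data frame with one row per accepted window: `start`, `end`,
#'   `resp_cpm`, `reliable`.
#' @examples
#' cl <- rejectArtifacts(simulateRRSeries(720, respFreq = 0.25, seed = 4))
#' colMeans(estimateRespirationRate(cl)["resp_cpm"])
#' @export
estimateRespirationRate <- function(clean, grid = NULL, interpRate = 4,
                                    respBand = c(0.12, 0.5), minRatio = 5,
                                    maxRejected = 0.2) {
  stopIfNot(is(clean, "RRSeries"), "need an RRSeries or CleanRRSeries")
  if (is.null(grid)) grid <- buildWindowGrid(duration(clean))
  grid <- windowUsability(clean, grid, maxRejected = maxRejected)
  acc <- which(grid$accepted)
  out <- data.frame(start = numeric(), end = numeric(),
                    resp_cpm = numeric(), reliable = logical())
  for (w in acc) {
    tach <- interpolateRR(clean, c(grid$start[w], grid$end[w]),
                          rate = interpRate)
    psd <- welchPsd(tach$rr, interpRate,
                    segLength = min(120, (grid$end[w] - grid$start[w]) / 3))
    r <- respFromPsd(psd, respBand, minRatio)
    out <- rbind(out, data.frame(start = grid$start[w], end = grid$end[w],
                                 resp_cpm = r$rate, reliable = r$reliable))
  }
  out
}
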