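#' Detect R peaks in a preprocessed ECG
#'
#' Pan-Tompkins style detector: zero-phase 5-15 Hz bandpass, differentiation,
#' squaring, 150 ms moving-window integration, then candidate selection as
#' local maxima of the integrated energy above a robust threshold with a 200
#' ms refractory period. Each candidate is refined to the local maximum of
#' the (bandpassed) ECG within ±100 ms, which pins the reported time to the
#' R wave itself.
#'
#' @param rec a preprocessed [EcgRecording] (see [preprocessEcg()]).
#' @param refractory minimum peak separation in seconds (default 0.2).
#' @param thresholdFrac threshold as a fraction of the robust QRS energy
#'   level (98th percentile of the integrated signal), default 0.3.
#' @return an [RPeakSeries]; flat or saturated input yields an empty series
#'   flagged `"flat_signal"`.
#' @examples
#' rr <- simulateRRSeries(30, seed = 2)
#' rec <- simulateEcg(rr, samplingRate = 1000, powerlineAmp = 0,
#'                    baselineWanderAmp = 0, seed = 2)$recording
#' length(detectRPeaks(rec))
#' @export
detectRPeaks <- function(rec, refractory = 0.2, thresholdFrac = 0.3) {
  stopIfNot(is(rec, "EcgRecording"), "rec must be an EcgRecording")
  fs <- rec@samplingRate
  x <- rec@samples
  if (sd(x) < 1e-9) {
    warning("flat or saturated signal; no peaks detected")
    return(RPeakSeries(numeric(), integer(), flags = "flat_signal"))
  }
  bp <- sosFiltfilt(butterSos(2, 5, fs, "high"), x)
  bp <- sosFiltfilt(butterSos(2, 15, fs, "low"), bp)
  der <- c(0, diff(bp)) * fs
  sq <- der^2
  w <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  qrsLevel <- quantile(integ, 0.98, names = FALSE)
  if (qrsLevel <= 0) {
    warning("no QRS energy found; no peaks detected")
    return(RPeakSeries(numeric(), integer(), flags = "flat_signal"))
  }
  thr <- thresholdFrac * qrsLevel
  cand <- localMaxima(integ, minDist = round(refractory * fs), thr = thr)
  if (!length(cand)) {
    warning("no candidate peaks above threshold")
    return(RPeakSeries(numeric(), integer(), flags = "no_peaks"))
  }
  half <- as.integer(round(0.1 * fs))
  n <- length(x)
  refined <- vapply(cand, function(i) {
    lo <- max(1L, as.integer(i) - half); hi <- min(n, as.integer(i) + half)
    lo + which.max(bp[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # re-impose the refractory period after refinement, keeping larger peaks
  kept <- integer()
  for (i in refined) {
    if (!length(kept) || (i - kept[length(kept)]) / fs >= refractory) {
      kept <- c(kept, i)
    } else if (bp[i] > bp[kept[length(kept)]]) {
      kept[length(kept)] <- i
    }
  }
  refined <- kept
  RPeakSeries(rec@t0 + (refined - 1L) / fs, as.integer(refined - 1L))
}

#' Build an R-R interval series from detected peaks
#'
#' @param peaks an [RPeakSeries] with at least two peaks.
#' @return an [RRSeries]: `interval[i] = 1000*(t[i+1] - t[i])` ms with onset
#'   `t[i]`.
#' @examples
#' rrFromPeaks(RPeakSeries(c(0, 0.8, 1.7)))
#' @export
rrFromPeaks <- function(peaks) {
  stopIfNot(is(peaks, "RPeakSeries"), "peaks must be an RPeakSeries")
  tt <- peakTimes(peaks)
  stopIfNot(length(tt) >= 2L, "need at least two peaks to form intervals")
  RRSeries(onsets = tt[-length(tt)], intervals = 1000 * diff(tt))
}

#' Screen an R-R series for artifacts by deviation deletion
#'
#' An interval is flagged deviant when it falls outside
#' `[minRR, maxRR]` ms or deviates from an 11-beat running median by more
#' than `maxDeviation` (proportion). Every flagged interval *and the
#' interval immediately following it* are deleted; this removes both halves
#' of the spurious split/merge that a missed or false beat produces. The
#' retained fraction is retained interval time over total interval time.
#'
#' @param rr an [RRSeries].
#' @param minRR,maxRR plausible interval range in ms (defaults 300, 2000).
#' @param maxDeviation maximal relative deviation from the running median
#'   (default 0.3).
#' @param medianWindow running-median width in beats (odd, default 11).
#' @return a [CleanRRSeries]. A retained fraction below 50% triggers a
#'   quality-gate warning; an empty result is an error.
#' @examples
#' rr <- RRSeries(c(0, .8, .805, 2.405, 3.215), c(800, 805, 1600, 810, 795))
#' ## the 1600 ms interval and its successor are deleted
#' suppressWarnings(rejectArtifacts(rr))
#' @export
rejectArtifacts <- function(rr, minRR = 300, maxRR = 2000,
                            maxDeviation = 0.3, medianWindow = 11) {
  stopIfNot(is(rr, "RRSeries"), "rr must be an RRSeries")
  x <- rrIntervals(rr)
  n <- length(x)
  stopIfNot(n >= 1L, "empty R-R series")
  k <- min(medianWindow, if (n %% 2L == 1L) n else n - 1L)
  med <- if (k >= 3L) runmed(x, k, endrule = "median") else x
  outOfRange <- x < minRR | x > maxRR
  deviant <- outOfRange | abs(x - med) / med > maxDeviation
  after <- c(FALSE, deviant[-n])
  valid <- !(deviant | after)
  reasons <- character(n)
  reasons[deviant & outOfRange] <- "range"
  reasons[deviant & !outOfRange] <- "deviation"
  reasons[after & !deviant] <- "post_deviant"
  rf <- sum(x[valid]) / sum(x)
  if (!any(valid)) {
    stop("all intervals were flagged as artifacts; nothing retained",
         call. = FALSE)
  }
  if (rf < 0.5) {
    warning(sprintf(
      "quality gate: only %.1f%% of recorded time retained", 100 * rf))
  }
  new("CleanRRSeries", onsets = rrOnsets(rr), intervals = x, valid = valid,
      meta = rr@meta, retainedFraction = rf, reasons = reasons)
}

#' Mean heart rate of a cleaned R-R series
#'
#' Computed from the mean retained interval (`60000 / mean(RR)` bpm), not as
#' the mean of instantaneous rates, so that a phase average matches
#' bpm-scale condition effects.
#'
#' @param clean a [CleanRRSeries].
#' @return heart rate in beats per minute.
#' @export
meanHeartRate <- function(clean) {
  stopIfNot(is(clean, "CleanRRSeries"), "clean must be a CleanRRSeries")
  x <- rrIntervals(clean)[rrValid(clean)]
  stopIfNot(length(x) >= 1L, "no retained intervals")
  60000 / mean(x)
}
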