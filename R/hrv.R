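#' Time-domain HRV: SDRR
#'
#' Sample standard deviation (n-1 denominator) of the retained R-R
#' intervals, conventionally computed over an entire recording phase.
#'
#' @param clean a [CleanRRSeries] (an [RRSeries] is accepted and treated as
#'   fully valid).
#' @return SDRR in ms.
#' @examples
#' sdrr(RRSeries(c(0, .8, 1.7), c(800, 900, 1000)))
#' @export
sdrr <- function(clean) {
  stopIfNot(is(clean, "RRSeries"), "need an RRSeries or CleanRRSeries")
  x <- rrIntervals(clean)[rrValid(clean)]
  stopIfNot(length(x) >= 2L, "need at least two retained intervals")
  sd(x)
}

#' Time-domain HRV: RMSSD
#'
#' Root mean square of successive differences of adjacent retained
#' intervals. Differences are only formed within gap-free runs: a pair whose
#' members straddle a deleted interval is never differenced.
#'
#' @inheritParams sdrr
#' @return RMSSD in ms.
#' @examples
#' rmssd(RRSeries(c(0, .8, 1.61), c(800, 810, 790)))
#' @export
rmssd <- function(clean) {
  stopIfNot(is(clean, "RRSeries"), "need an RRSeries or CleanRRSeries")
  x <- rrIntervals(clean)
  v <- rrValid(clean)
  n <- length(x)
  stopIfNot(n >= 2L, "need at least two intervals")
  pair <- v[-n] & v[-1L]
  stopIfNot(any(pair), "no adjacent pair of retained intervals")
  d <- diff(x)[pair]
  sqrt(mean(d^2))
}

#' Sliding-window grid for frequency-domain HRV
#'
#' Windows of `windowLength` seconds advancing in steps of `step` seconds:
#' starts 0, step, 2*step, ... while `start + windowLength <= duration`.
#'
#' @param phaseDuration phase length in seconds (at least one window).
#' @param windowLength window length in seconds (default 360 = 6 min).
#' @param step step in seconds (default 30).
#' @return a data frame with columns `start`, `end`.
#' @examples
#' nrow(buildWindowGrid(1800))   # 49 windows
#' @export
buildWindowGrid <- function(phaseDuration, windowLength = 360, step = 30) {
  stopIfNot(windowLength > 0 && step > 0, "window and step must be positive")
  stopIfNot(phaseDuration >= windowLength,
            "phase shorter than a single analysis window")
  starts <- seq(0, phaseDuration - windowLength, by = step)
  data.frame(start = starts, end = starts + windowLength)
}

#' Window usability under the 20% rejection rule
#'
#' For each window the usable fraction is the retained interval time
#' overlapping the window divided by the window length; a window is accepted
#' when at most `maxRejected` of it is rejected (or uncovered) and it holds
#' at least `minAnchors` retained intervals.
#'
#' @param clean a [CleanRRSeries].
#' @param grid a [buildWindowGrid()] data frame.
#' @param maxRejected maximal rejected fraction (default 0.2).
#' @param minAnchors minimal retained anchor count (default 4).
#' @return `grid` with columns `usable_fraction` and `accepted` appended.
#' @export
windowUsability <- function(clean, grid, maxRejected = 0.2, minAnchors = 4) {
  stopIfNot(is(clean, "RRSeries"), "need an RRSeries or CleanRRSeries")
  on <- rrOnsets(clean)
  x <- rrIntervals(clean)
  v <- rrValid(clean)
  iLo <- on[v]
  iHi <- on[v] + x[v] / 1000
  anchors <- iHi  # interval end = time of the closing beat
  grid$usable_fraction <- vapply(seq_len(nrow(grid)), function(w) {
    ov <- pmin(iHi, grid$end[w]) - pmax(iLo, grid$start[w])
    sum(ov[ov > 0]) / (grid$end[w] - grid$start[w])
  }, numeric(1))
  nAnch <- vapply(seq_len(nrow(grid)), function(w) {
    sum(anchors >= grid$start[w] & anchors <= grid$end[w])
  }, numeric(1))
  grid$accepted <- (1 - grid$usable_fraction) <= maxRejected &
    nAnch >= minAnchors
  grid
}

#' Cubic-spline tachogram on a uniform grid
#'
#' Interpolates the retained R-R intervals (anchored at the time of each
#' interval's closing beat) with a cubic spline evaluated on a uniform grid
#' across one analysis window. Values outside the anchor range are held at
#' the boundary value rather than extrapolated.
#'
#' @param clean a [CleanRRSeries].
#' @param window numeric `c(start, end)` in seconds.
#' @param rate interpolation rate in Hz (default 4).
#' @return a list with `time` (s), `rr` (ms) and `rate`.
#' @export
interpolateRR <- function(clean, window, rate = 4) {
  stopIfNot(is(clean, "RRSeries"), "need an RRSeries or CleanRRSeries")
  stopIfNot(length(window) == 2L && window[2] > window[1],
            "window must be c(start, end)")
  on <- rrOnsets(clean)
  x <- rrIntervals(clean)
  v <- rrValid(clean)
  anchors <- on[v] + x[v] / 1000
  vals <- x[v]
  sel <- anchors >= window[1] - 5 & anchors <= window[2] + 5
  stopIfNot(sum(sel) >= 4L, "need at least 4 anchor points in the window")
  nOut <- round((window[2] - window[1]) * rate)
  tout <- window[1] + (seq_len(nOut) - 1L) / rate
  sp <- spline(anchors[sel], vals[sel], xout = tout, method = "fmm")
  y <- sp$y
  lo <- tout < min(anchors[sel])
  hi <- tout > max(anchors[sel])
  if (any(lo)) y[lo] <- vals[sel][1L]
  if (any(hi)) y[hi] <- vals[sel][sum(sel)]
  list(time = tout, rr = y, rate = rate)
}

#' Welch power spectral density
#'
#' Mean-removed Welch periodogram with Hann-windowed segments and 50%
#' overlap; one-sided density scaled so that the integral of the PSD over
#' frequency equals the signal variance (Parseval).
#'
#' @param x numeric signal (uniformly sampled).
#' @param rate sampling rate (Hz).
#' @param segLength segment length in seconds (default 120).
#' @param overlap fractional segment overlap (default 0.5).
#' @return a data frame with columns `freq` (Hz) and `psd` (ms^2/Hz for a
#'   tachogram input).
#' @export
welchPsd <- function(x, rate, segLength = 120, overlap = 0.5) {
  nseg <- round(segLength * rate)
  stopIfNot(nseg >= 8, "segment too short")
  stopIfNot(length(x) >= nseg, "signal shorter than one segment")
  x <- x - mean(x)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  U <- sum(w^2)
  nf <- nseg %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf + 1L)]
    acc <- acc + (Mod(X)^2) / (U * rate)
  }
  p <- acc / length(starts)
  # fold the two-sided density into one side (all bins but DC/Nyquist twice)
  p[2:(nf + if (nseg %% 2L == 0L) 0L else 1L)] <-
    2 * p[2:(nf + if (nseg %% 2L == 0L) 0L else 1L)]
  data.frame(freq = (0:nf) * rate / nseg, psd = p)
}

#' Band power from a Welch PSD
#'
#' Integrates the PSD over the half-open band `[lo, hi)` by the rectangle
#' rule on the Welch frequency grid.
#'
#' @param psd a [welchPsd()] data frame (or a tachogram list from
#'   [interpolateRR()], which is transformed first).
#' @param band numeric `c(lo, hi)` in Hz.
#' @param rate required when `psd` is a raw tachogram list.
#' @return band power (ms^2 for a tachogram).
#' @export
welchBandPower <- function(psd, band, rate = NULL) {
  if (is.list(psd) && !is.data.frame(psd) && !is.null(psd$rr)) {
    psd <- welchPsd(psd$rr, psd$rate)
  }
  stopIfNot(is.data.frame(psd) && all(c("freq", "psd") %in% names(psd)),
            "psd must come from welchPsd()")
  stopIfNot(length(band) == 2L && band[1] >= 0 && band[2] > band[1],
            "band must be c(lo, hi) with 0 <= lo < hi")
  stopIfNot(band[2] <= max(psd$freq) + 1e-9,
            "band exceeds the Nyquist frequency")
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= band[1] & psd$freq < band[2]
  sum(psd$psd[sel]) * df
}

#' Per-phase HRV summary
#'
#' Time-domain indices (HR, SDRR, RMSSD) over the whole phase; HF, LF,
#' LF/HF and respiration rate as means over the accepted 6-min/30-s
#' windows (LF/HF is computed per window, then averaged). Frequency-domain
#' fields are `NA` when no window is accepted.
#'
#' @param clean a [CleanRRSeries] for one phase.
#' @param windowLength,step sliding-window protocol (s), defaults 360/30.
#' @param interpRate tachogram interpolation rate (Hz, default 4).
#' @param maxRejected window rejection rule (default 0.2).
#' @param hfBand,lfBand frequency bands in Hz, half-open.
#' @param respBand respiration search band in Hz.
#' @return a one-row data frame: `hr`, `sdrr`, `rmssd`, `hf`, `lf`, `lfhf`,
#'   `resp_cpm`, `resp_reliable`, `n_windows_used`, `retained_fraction`,
#'   plus any subject/condition/side/phase labels found in the metadata.
#' @examples
#' cl <- rejectArtifacts(simulateRRSeries(720, seed = 3))
#' phaseHrvSummary(cl)
#' @export
phaseHrvSummary <- function(clean, windowLength = 360, step = 30,
                            interpRate = 4, maxRejected = 0.2,
                            hfBand = c(0.15, 0.4), lfBand = c(0.04, 0.15),
                            respBand = c(0.12, 0.5)) {
  stopIfNot(is(clean, "CleanRRSeries"), "clean must be a CleanRRSeries")
  total <- duration(clean)
  hf <- lf <- lfhf <- respRate <- NA_real_
  respReliable <- FALSE
  nUsed <- 0L
  if (total >= windowLength) {
    grid <- windowUsability(clean,
                            buildWindowGrid(total, windowLength, step),
                            maxRejected = maxRejected)
    acc <- which(grid$accepted)
    nUsed <- length(acc)
    if (nUsed > 0L) {
      hfW <- lfW <- ratioW <- respW <- numeric(0)
      respOk <- logical(0)
      for (w in acc) {
        tach <- interpolateRR(clean, c(grid$start[w], grid$end[w]),
                              rate = interpRate)
        psd <- welchPsd(tach$rr, interpRate,
                        segLength = min(120, windowLength / 3))
        hfw <- welchBandPower(psd, hfBand)
        lfw <- welchBandPower(psd, lfBand)
        hfW <- c(hfW, hfw)
        lfW <- c(lfW, lfw)
        ratioW <- c(ratioW, if (hfw > 0) lfw / hfw else NA_real_)
        rw <- respFromPsd(psd, respBand)
        respW <- c(respW, rw$rate)
        respOk <- c(respOk, rw$reliable)
      }
      hf <- mean(hfW)
      lf <- mean(lfW)
      lfhf <- if (all(is.na(ratioW))) NA_real_ else mean(ratioW, na.rm = TRUE)
      if (any(respOk)) {
        respRate <- mean(respW[respOk])
        respReliable <- TRUE
      }
    }
  }
  out <- data.frame(
    hr = meanHeartRate(clean),
    sdrr = sdrr(clean),
    rmssd = rmssd(clean),
    hf = hf, lf = lf, lfhf = lfhf,
    resp_cpm = respRate, resp_reliable = respReliable,
    n_windows_used = nUsed,
    retained_fraction = retainedFraction(clean))
  labs <- clean@meta[intersect(c("subject", "session", "condition", "side",
                                 "phase"), names(clean@meta))]
  if (length(labs)) out <- cbind(as.data.frame(labs), out)
  out
}
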