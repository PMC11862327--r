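#' @import methods
#' @importFrom stats approx binom.test fft median model.matrix pf pt qf
#'   quantile rnorm rpois runif runmed sd spline dt dcauchy coef
#'   integrate p.adjust setNames
#' @importFrom utils head read.csv tail write.csv
#' @importFrom tools file_ext
NULL

#' ECG recording container
#'
#' A uniformly sampled single-lead ECG voltage trace with its sampling rate,
#' start time and study metadata (subject, session, condition, side, phase).
#' Voltages are stored in microvolts throughout the package.
#'
#' @slot samples numeric vector of ECG samples (µV).
#' @slot samplingRate sampling rate in Hz.
#' @slot t0 start time in seconds.
#' @slot meta named list of labels (e.g. subject, session, condition, side,
#'   phase) plus any simulator ground truth.
#'
#' @examples
#' rec <- EcgRecording(sin(2 * pi * 1 * seq(0, 1, by = 1 / 500)), 500)
#' duration(rec)
#' @export
setClass("EcgRecording",
  representation(
    samples = "numeric",
    samplingRate = "numeric",
    t0 = "numeric",
    meta = "list"
  ),
  prototype(t0 = 0, meta = list())
)

setValidity("EcgRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive number")
  }
  if (length(object@samples) == 0L) {
    msg <- c(msg, "recording must contain at least one sample")
  }
  if (any(!is.finite(object@samples))) {
    msg <- c(msg, "samples must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' @param samples numeric vector of ECG samples (µV).
#' @param samplingRate sampling rate in Hz.
#' @param t0 start time in seconds.
#' @param meta named list of metadata labels.
#' @rdname EcgRecording-class
#' @export
EcgRecording <- function(samples, samplingRate, t0 = 0, meta = list()) {
  new("EcgRecording", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate), t0 = as.numeric(t0),
      meta = meta)
}

#' Detected R-peak series
#'
#' Times (seconds) and 0-based sample indices of detected R peaks, strictly
#' increasing.
#'
#' @slot peakTimes numeric, seconds.
#' @slot peakIndices integer, 0-based sample positions.
#' @slot flags character vector of detector warnings (e.g. "flat_signal").
#' @export
setClass("RPeakSeries",
  representation(
    peakTimes = "numeric",
    peakIndices = "integer",
    flags = "character"
  ),
  prototype(flags = character())
)

setValidity("RPeakSeries", function(object) {
  msg <- character()
  if (length(object@peakTimes) != length(object@peakIndices)) {
    msg <- c(msg, "peakTimes and peakIndices must have equal length")
  }
  if (length(object@peakTimes) > 1L && any(diff(object@peakTimes) <= 0)) {
    msg <- c(msg, "peakTimes must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' @param peakTimes numeric vector of peak times (s).
#' @param peakIndices integer vector of 0-based sample indices.
#' @param flags character vector of detector flags.
#' @rdname RPeakSeries-class
#' @export
RPeakSeries <- function(peakTimes, peakIndices = integer(), flags = character()) {
  if (!length(peakIndices) && length(peakTimes)) {
    peakIndices <- integer(length(peakTimes))
  }
  new("RPeakSeries", peakTimes = as.numeric(peakTimes),
      peakIndices = as.integer(peakIndices), flags = flags)
}

#' R-R interval series
#'
#' Beat-to-beat intervals in milliseconds with the onset time (seconds) of
#' each interval, i.e. the time of the R peak opening the interval. A logical
#' mask marks intervals that survive artifact screening; in a freshly built
#' series all intervals are valid.
#'
#' @slot onsets numeric, interval onset times (s), increasing.
#' @slot intervals numeric, R-R intervals (ms), positive.
#' @slot valid logical mask, one entry per interval.
#' @slot meta named list (simulation ground truth, provenance).
#' @export
setClass("RRSeries",
  representation(
    onsets = "numeric",
    intervals = "numeric",
    valid = "logical",
    meta = "list"
  ),
  prototype(meta = list())
)

setValidity("RRSeries", function(object) {
  msg <- character()
  n <- length(object@intervals)
  if (length(object@onsets) != n) {
    msg <- c(msg, "onsets and intervals must have equal length")
  }
  if (length(object@valid) != n) {
    msg <- c(msg, "valid mask must have one entry per interval")
  }
  if (n > 0L && any(object@intervals <= 0)) {
    msg <- c(msg, "intervals must be positive")
  }
  if (n > 1L && any(diff(object@onsets) <= 0)) {
    msg <- c(msg, "onsets must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' @param onsets numeric vector of interval onset times (s).
#' @param intervals numeric vector of R-R intervals (ms).
#' @param valid logical mask (defaults to all valid).
#' @param meta named list.
#' @rdname RRSeries-class
#' @export
RRSeries <- function(onsets, intervals, valid = rep(TRUE, length(intervals)),
                     meta = list()) {
  new("RRSeries", onsets = as.numeric(onsets),
      intervals = as.numeric(intervals), valid = as.logical(valid),
      meta = meta)
}

#' Artifact-screened R-R series
#'
#' An [RRSeries] after deviation deletion: deleted intervals keep their slots
#' but are masked invalid and carry a reason code; `retainedFraction` is the
#' retained time divided by the total recorded time.
#'
#' @slot retainedFraction proportion of total interval time kept, in (0, 1].
#' @slot reasons character per interval: `""` kept, otherwise a reason code
#'   (`"range"`, `"deviation"`, `"post_deviant"`, `"detector_gap"`).
#' @export
setClass("CleanRRSeries",
  contains = "RRSeries",
  representation(
    retainedFraction = "numeric",
    reasons = "character"
  )
)

setValidity("CleanRRSeries", function(object) {
  msg <- character()
  if (length(object@retainedFraction) != 1L ||
      object@retainedFraction < 0 || object@retainedFraction > 1) {
    msg <- c(msg, "retainedFraction must lie in [0, 1]")
  }
  if (length(object@reasons) != length(object@intervals)) {
    msg <- c(msg, "reasons must have one entry per interval")
  }
  if (any(!object@valid & !nzchar(object@reasons))) {
    msg <- c(msg, "every deleted interval must carry a reason code")
  }
  if (length(msg)) msg else TRUE
})
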