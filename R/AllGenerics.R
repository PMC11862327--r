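#' @rdname EcgRecording-class
#' @param object,x an object.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EcgRecording-class
#' @export
setGeneric("ecgSamples", function(x) standardGeneric("ecgSamples"))

#' @rdname EcgRecording-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname EcgRecording-class
#' @export
setGeneric("recordingMeta", function(x) standardGeneric("recordingMeta"))

#' @rdname RPeakSeries-class
#' @export
setGeneric("peakTimes", function(x) standardGeneric("peakTimes"))

#' @rdname RRSeries-class
#' @export
setGeneric("rrOnsets", function(x) standardGeneric("rrOnsets"))

#' @rdname RRSeries-class
#' @export
setGeneric("rrIntervals", function(x) standardGeneric("rrIntervals"))

#' @rdname RRSeries-class
#' @export
setGeneric("rrValid", function(x) standardGeneric("rrValid"))

#' @rdname CleanRRSeries-class
#' @export
setGeneric("retainedFraction", function(x) standardGeneric("retainedFraction"))

#' @rdname CleanRRSeries-class
#' @export
setGeneric("rejectReasons", function(x) standardGeneric("rejectReasons"))

#' @rdname EcgRecording-class
setMethod("samplingRate", "EcgRecording", function(x) x@samplingRate)

#' @rdname EcgRecording-class
setMethod("ecgSamples", "EcgRecording", function(x) x@samples)

#' @rdname EcgRecording-class
setMethod("duration", "EcgRecording",
          function(x) length(x@samples) / x@samplingRate)

#' @rdname EcgRecording-class
setMethod("recordingMeta", "EcgRecording", function(x) x@meta)

#' @rdname EcgRecording-class
setMethod("length", "EcgRecording", function(x) length(x@samples))

#' @rdname RPeakSeries-class
setMethod("peakTimes", "RPeakSeries", function(x) x@peakTimes)

#' @rdname RPeakSeries-class
setMethod("length", "RPeakSeries", function(x) length(x@peakTimes))

#' @rdname RRSeries-class
setMethod("rrOnsets", "RRSeries", function(x) x@onsets)

#' @rdname RRSeries-class
setMethod("rrIntervals", "RRSeries", function(x) x@intervals)

#' @rdname RRSeries-class
setMethod("rrValid", "RRSeries", function(x) x@valid)

#' @rdname RRSeries-class
setMethod("length", "RRSeries", function(x) length(x@intervals))

#' @rdname RRSeries-class
setMethod("duration", "RRSeries", function(x) sum(x@intervals) / 1000)

#' @rdname CleanRRSeries-class
setMethod("retainedFraction", "CleanRRSeries", function(x) x@retainedFraction)

#' @rdname CleanRRSeries-class
setMethod("rejectReasons", "CleanRRSeries", function(x) x@reasons)

setMethod("show", "EcgRecording", function(object) {
  m <- object@meta
  lab <- paste(unlist(m[intersect(c("subject", "condition", "side", "phase"),
                                  names(m))]), collapse = " / ")
  cat(sprintf("EcgRecording: %d samples @ %g Hz (%.1f s)%s\n",
              length(object@samples), object@samplingRate,
              duration(object),
              if (nzchar(lab)) paste0(" [", lab, "]") else ""))
})

setMethod("show", "RPeakSeries", function(object) {
  cat(sprintf("RPeakSeries: %d peaks%s\n", length(object@peakTimes),
              if (length(object@flags))
                paste0(" (flags: ", paste(object@flags, collapse = ", "), ")")
              else ""))
})

setMethod("show", "RRSeries", function(object) {
  cat(sprintf("RRSeries: %d intervals, mean RR %.1f ms, %.1f s\n",
              length(object@intervals),
              if (length(object@intervals)) mean(object@intervals) else NA,
              duration(object)))
})

setMethod("show", "CleanRRSeries", function(object) {
  cat(sprintf(
    "CleanRRSeries: %d/%d intervals retained (%.1f%% of recorded time)\n",
    sum(object@valid), length(object@intervals),
    100 * object@retainedFraction))
})
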