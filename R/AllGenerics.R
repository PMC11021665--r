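#' @include AllClasses.R
NULL

#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @export
setGeneric("pnTimes", function(x) standardGeneric("pnTimes"))
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' Classify one packet of preprocessed EEG
#'
#' Applies a trained per-sample detector to a channels x T packet and
#' returns the packet decision: one 0/1 label per sample plus the positive
#' count, the quantity the real-time trigger rule operates on.
#'
#' @param model a trained [MLPDetector-class] or [LSTMDetector-class].
#' @param packet numeric matrix (channels x samples), rows named or ordered
#'   as `channels(model)`.
#' @return list with `labels` (integer vector), `positive_count`, `length`.
#' @export
setGeneric("classifyPacket", function(model, packet) standardGeneric("classifyPacket"))

# --------------------------------------------------------------- accessors

#' @describeIn Montage-class channel labels
#' @param x object.
#' @export
setMethod("channelNames", "Montage", function(x) x@labels)
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@montage@labels)
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)
#' @export
setMethod("channelNames", "DetectorModel", function(x) x@channels)

#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@rate)

#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @export
setMethod("eegData", "EpochSet", function(x) x@data)

#' @export
setMethod("events", "EEGRecording", function(x) x@events)

#' @export
setMethod("montage", "EEGRecording", function(x) x@montage)

#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1])
#' @export
setMethod("nTrials", "SessionBundle", function(x)
  sum(vapply(x@recordings, function(r) sum(r@events$code == TRIG_TRIAL_START), integer(1))))

#' @export
setMethod("groundTruth", "SessionBundle", function(x) x@groundTruth)

#' @export
setMethod("epochLabels", "EpochSet", function(x) x@labels)

#' @export
setMethod("pnTimes", "CalibrationResult", function(x) x@pnTimesMs)

#' @export
setMethod("trainingHistory", "MLPDetector", function(x) x@history)
#' @export
setMethod("trainingHistory", "LSTMDetector", function(x) x@history)

# ------------------------------------------------------------ show methods

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage with %d channels (%s ... %s)\n",
              length(object@labels), object@labels[1],
              tail(object@labels, 1)))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(object@data), ncol(object@data), object@rate,
              ncol(object@data) / object@rate, nrow(object@events)))
})

setMethod("show", "SessionBundle", function(object) {
  cat(sprintf("SessionBundle '%s': %d blocks, %d trials, ground truth: %s\n",
              object@sessionId, length(object@recordings), nTrials(object),
              if (nrow(object@groundTruth)) "yes" else "no"))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples, [%g, %g) ms rel. %s%s\n",
              d[1], d[2], d[3], object@windowMs[1], object@windowMs[2],
              object@align,
              if (nrow(object@labels)) ", labeled" else ""))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: %d trials, avg PN %.1f ms, threshold %.3g uV (k=%g), scheme %s\n",
              length(object@pnTimesMs), object@avgPnMs,
              object@thresholdValue, object@thresholdK, object@scheme))
})

setMethod("show", "ThresholdDetector", function(object) {
  cat(sprintf("ThresholdDetector on %s: threshold %.3g uV (k=%g, %s polarity)\n",
              paste(object@channels, collapse = ","), object@threshold,
              object@k, if (object@negatePolarity) "negated" else "raw"))
})

setMethod("show", "AveragePNDetector", function(object) {
  cat(sprintf("AveragePNDetector: fires at %.1f ms (open loop)\n", object@avgPnMs))
})

setMethod("show", "MLPDetector", function(object) {
  cat(sprintf("MLPDetector: %d inputs, hidden [%s], %d epochs trained\n",
              length(object@channels),
              paste(object@config$hidden, collapse = ", "),
              length(object@history)))
})

setMethod("show", "LSTMDetector", function(object) {
  cat(sprintf("LSTMDetector: %d inputs, %d hidden units%s, %d epochs trained\n",
              length(object@channels), object@config$hidden,
              if (length(object@frozen)) " (transferred, frozen base)" else "",
              length(object@history)))
})

setMethod("show", "SessionReport", function(object) {
  cat(sprintf("SessionReport: %d trials | accuracy %.1f%% | FP %.1f%% | FN %.1f%%\n",
              nrow(object@trials), object@accuracy, object@fpRate, object@fnRate))
  print(object@counts)
})
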