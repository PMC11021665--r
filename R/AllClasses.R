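#' @include mrcpbci-package.R
NULL

#' Montage: channel labels, scalp positions, and neighbor relation
#'
#' Ordered channel names from the extended 10-20 system together with 2-D
#' scalp coordinates (unitless head-circle convention, vertex at the origin)
#' and a symmetric nearest-neighbor adjacency used by the surface Laplacian.
#'
#' @slot labels character vector of unique channel names.
#' @slot positions numeric matrix (channels x 2) of x/y scalp coordinates,
#'   rows named by label.
#' @slot neighbors named list mapping each label to its adjacent labels.
#' @seealso [standardMontage()], [validateMontage()]
#' @export
setClass("Montage", representation(
  labels    = "character",
  positions = "matrix",
  neighbors = "list"
))

setValidity("Montage", function(object) {
  lab <- object@labels
  if (anyDuplicated(lab)) return("duplicate channel labels")
  if (nrow(object@positions) != length(lab)) return("positions/labels mismatch")
  if (!identical(rownames(object@positions), lab))
    return("positions rows must be named by label, in order")
  if (!identical(sort(names(object@neighbors)), sort(lab)))
    return("neighbors must be keyed by every label")
  for (ch in lab) {
    nb <- object@neighbors[[ch]]
    if (!all(nb %in% lab)) return("neighbor is not a montage label")
    for (o in nb) if (!ch %in% object@neighbors[[o]])
      return(sprintf("neighbor relation not symmetric (%s -> %s)", ch, o))
  }
  TRUE
})

#' EEGRecording: a multi-channel EEG stream with trigger events
#'
#' Amplitudes are stored in microvolts as a channels x samples matrix with
#' 0-based trigger sample indices. Protocol events use codes 8 (trial
#' start), 6 (preparation start, the real-time clock zero) and 7 (block
#' end); other codes are preserved but ignored by [extractTrials()].
#'
#' @slot data numeric matrix (channels x samples), rows named by label, uV.
#' @slot rate sampling rate in Hz.
#' @slot montage a [Montage-class] whose labels match the data rows.
#' @slot events data.frame with integer columns `code` and `sample`
#'   (0-based, strictly within the recording).
#' @export
setClass("EEGRecording", representation(
  data    = "matrix",
  rate    = "numeric",
  montage = "Montage",
  events  = "data.frame"
))

setValidity("EEGRecording", function(object) {
  if (length(object@rate) != 1 || object@rate <= 0) return("rate must be > 0")
  if (nrow(object@data) != length(object@montage@labels))
    return("data rows must equal number of montage labels")
  if (!identical(rownames(object@data), object@montage@labels))
    return("data row names must equal montage labels")
  ev <- object@events
  if (!all(c("code", "sample") %in% names(ev)))
    return("events needs columns code, sample")
  if (nrow(ev) && (any(ev$sample < 0) || any(ev$sample >= ncol(object@data))))
    return("event sample indices must lie within [0, samples)")
  TRUE
})

#' SessionBundle: a simulated or recorded session of training blocks
#'
#' One [EEGRecording-class] per block (five trials each under the standard
#' protocol), an identifier, and - for synthetic sessions - the simulator's
#' ground truth: the true PN latency (ms relative to preparation start) and
#' template peak amplitude per trial.
#'
#' @slot recordings list of [EEGRecording-class], one per block.
#' @slot sessionId character identifier.
#' @slot groundTruth data.frame with columns `block`, `trial`, `pn_ms`,
#'   `amplitude` (0 rows when unknown).
#' @slot plan the session plan the bundle was generated from (empty list
#'   for real recordings).
#' @export
setClass("SessionBundle", representation(
  recordings  = "list",
  sessionId   = "character",
  groundTruth = "data.frame",
  plan        = "list"
))

setValidity("SessionBundle", function(object) {
  ok <- vapply(object@recordings, function(r) is(r, "EEGRecording"), logical(1))
  if (!all(ok)) return("recordings must all be EEGRecording")
  if (nrow(object@groundTruth)) {
    need <- c("block", "trial", "pn_ms")
    if (!all(need %in% names(object@groundTruth)))
      return("groundTruth needs columns block, trial, pn_ms")
  }
  TRUE
})

#' EpochSet: per-trial epochs with optional per-sample class labels
#'
#' Epochs are aligned either to preparation start (trigger 6) or to the cue
#' to move (preparation start + 3000 ms); the window is half-open in ms.
#' Labels, when present, are an integer trials x samples matrix with 0 =
#' rest, 1 = motor intent, NA = unlabeled (excluded from training).
#'
#' @slot data numeric array trials x channels x samples (uV).
#' @slot rate sampling rate in Hz.
#' @slot channels channel labels (second dimension).
#' @slot windowMs length-2 numeric, half-open window in ms relative to the
#'   alignment event.
#' @slot align "prep_start" or "cue".
#' @slot labels integer matrix trials x samples or 0-row matrix when absent.
#' @slot refsMs per-trial labeling reference time (ms relative to prep
#'   start); length 0 when unlabeled.
#' @export
setClass("EpochSet", representation(
  data     = "array",
  rate     = "numeric",
  channels = "character",
  windowMs = "numeric",
  align    = "character",
  labels   = "matrix",
  refsMs   = "numeric"
))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be trials x channels x samples")
  if (d[2] != length(object@channels)) return("channel dimension mismatch")
  if (length(object@windowMs) != 2) return("windowMs must have length 2")
  if (!object@align %in% c("prep_start", "cue")) return("unknown alignment")
  if (nrow(object@labels) && !identical(dim(object@labels), d[c(1, 3)]))
    return("labels must be trials x samples")
  if (nrow(object@labels)) {
    v <- object@labels[!is.na(object@labels)]
    if (length(v) && !all(v %in% c(0L, 1L)))
      return("labels must be 0 (rest), 1 (motor intent) or NA")
  }
  TRUE
})

#' CalibrationResult: per-trial PN latencies, ERP, and detector thresholds
#'
#' @slot pnTimesMs per-trial PN latency in ms relative to preparation start
#'   (each inside the detection window, 2500-3500 ms).
#' @slot avgPnMs arithmetic mean of `pnTimesMs`.
#' @slot erp channels x samples average epoch (the calibration ERP/MRCP).
#' @slot erpWindowMs epoch window of the ERP (ms relative to prep start).
#' @slot rate sampling rate in Hz.
#' @slot thresholdValue threshold in uV on the polarity-adjusted Cz series.
#' @slot thresholdK the SD multiplier used (1, 2 or 3).
#' @slot scheme labeling scheme used downstream ("time_based"/"pn_based").
#' @export
setClass("CalibrationResult", representation(
  pnTimesMs      = "numeric",
  avgPnMs        = "numeric",
  erp            = "matrix",
  erpWindowMs    = "numeric",
  rate           = "numeric",
  thresholdValue = "numeric",
  thresholdK     = "numeric",
  scheme         = "character"
))

setValidity("CalibrationResult", function(object) {
  if (length(object@pnTimesMs) &&
      abs(object@avgPnMs - mean(object@pnTimesMs)) > 1e-9)
    return("avgPnMs must be the mean of pnTimesMs")
  TRUE
})

#' DetectorModel: common interface of the four motor-intent detectors
#'
#' Virtual parent of [ThresholdDetector-class], [AveragePNDetector-class],
#' [MLPDetector-class] and [LSTMDetector-class]. Every detector stores the
#' channel list it expects and is serializable with [saveDetector()] /
#' [readDetector()] with identical behavior after reload.
#'
#' @slot channels input channel labels, in order.
#' @slot seed training seed (NA for the non-trained detectors).
#' @export
setClass("DetectorModel", representation("VIRTUAL",
  channels = "character",
  seed     = "numeric"
))

#' @describeIn DetectorModel-class fires when the packet mean of the
#'   (polarity-adjusted) Cz series exceeds the calibration threshold.
#' @slot threshold threshold value in uV.
#' @slot k SD multiplier chosen during calibration.
#' @slot negatePolarity if TRUE (default) the detector operates on the
#'   negated series so the negative PN peak becomes a positive excursion.
#' @export
setClass("ThresholdDetector", contains = "DetectorModel", representation(
  threshold      = "numeric",
  k              = "numeric",
  negatePolarity = "logical"
))

#' @describeIn DetectorModel-class open-loop detector that fires at the
#'   average calibration PN time, ignoring the EEG.
#' @slot avgPnMs mean calibration PN latency (ms relative to prep start).
#' @export
setClass("AveragePNDetector", contains = "DetectorModel", representation(
  avgPnMs = "numeric"
))

#' @describeIn DetectorModel-class multilayer perceptron labeling each
#'   sample from its instantaneous channel vector.
#' @slot params network weights.
#' @slot config the [mlpConfig()] used for training.
#' @slot norm per-channel z-normalization state (empty list if none).
#' @slot history training loss per epoch.
#' @export
setClass("MLPDetector", contains = "DetectorModel", representation(
  params  = "list",
  config  = "list",
  norm    = "list",
  history = "numeric"
))

#' @describeIn DetectorModel-class bidirectional LSTM sequence labeler;
#'   when `frozen` is non-empty the model is a transferred stack whose
#'   frozen base layer feeds a newly trained bidirectional layer.
#' @slot params weights of the (trainable) BiLSTM + softmax readout.
#' @slot config the [lstmConfig()] used for training.
#' @slot norm per-channel z-normalization state (empty list if none).
#' @slot history training loss per epoch.
#' @slot frozen frozen base-layer weights for transferred models.
#' @export
setClass("LSTMDetector", contains = "DetectorModel", representation(
  params  = "list",
  config  = "list",
  norm    = "list",
  history = "numeric",
  frozen  = "list"
))

#' SessionReport: per-trial trigger outcomes and session-level rates
#'
#' @slot trials data.frame with one row per trial: `block`, `trial`,
#'   `time_ms` (decision timestamp relative to prep start), `category`
#'   (true_positive / false_positive / fallback / none) and `fn` (offline
#'   false-negative flag).
#' @slot fpRate percentage of trials triggered in the rest window.
#' @slot fnRate percentage of trials flagged false-negative offline.
#' @slot accuracy percentage of trials triggered in the PN window.
#' @slot counts named integer vector (tp, fp, fallback, none).
#' @export
setClass("SessionReport", representation(
  trials   = "data.frame",
  fpRate   = "numeric",
  fnRate   = "numeric",
  accuracy = "numeric",
  counts   = "numeric"
))

setValidity("SessionReport", function(object) {
  n <- nrow(object@trials)
  if (n && sum(object@counts) != n)
    return("category counts must partition the trials")
  TRUE
})
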