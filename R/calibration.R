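#' @include preprocess.R
NULL

#' Labeling scheme for supervised training data
#'
#' Time-based labeling uses the cue to move as the per-trial reference;
#' PN-based labeling uses each trial's own PN latency. One second around
#' the reference (`[ref - 500, ref + 500)` ms) is motor intent; the second
#' preceding it (`[ref - 1500, ref - 500)`) is rest; everything else is
#' unlabeled and excluded from training.
#'
#' @param kind "time_based" or "pn_based".
#' @param intent_halfwidth_ms half-width of the motor-intent window.
#' @param rest_duration_ms duration of the rest window.
#' @export
labelingScheme <- function(kind = c("time_based", "pn_based"),
                           intent_halfwidth_ms = 500,
                           rest_duration_ms = 1000) {
  kind <- match.arg(kind)
  list(kind = kind, intent_halfwidth_ms = intent_halfwidth_ms,
       rest_duration_ms = rest_duration_ms)
}

#' Per-trial PN latency from a virtual-Cz series
#'
#' The trial PN is the time of the minimum (maximum negative value) of the
#' series within the detection window, the closed interval from 500 ms
#' before to 500 ms after the cue to move. Ties break to the earliest
#' sample.
#'
#' @param x numeric series (one trial) starting at `startMs`.
#' @param cueMs cue time on the same time axis as `startMs`.
#' @param rate sampling rate (Hz).
#' @param startMs time of `x[1]`.
#' @param halfWidthMs detection-window half width.
#' @return PN time in ms (same axis as `cueMs`), on the sample grid.
#' @export
trialPnTime <- function(x, cueMs, rate, startMs = 0, halfWidthMs = 500) {
  from <- msToSamples(cueMs - halfWidthMs - startMs, rate)
  to <- msToSamples(cueMs + halfWidthMs - startMs, rate)
  if (from < 0 || to >= length(x))
    stop("detection window not covered by the epoch")
  seg <- x[(from + 1L):(to + 1L)]
  startMs + (from + which.min(seg) - 1L) * 1000 / rate
}

#' Mean calibration PN latency
#'
#' @param pnTimesMs per-trial PN latencies (ms).
#' @return their arithmetic mean, the open-loop trigger time of the
#'   average-PN detector.
#' @export
averagePn <- function(pnTimesMs) {
  if (!length(pnTimesMs)) stop("no PN times to average")
  mean(pnTimesMs)
}

#' Calibration ERP: pointwise average across trials
#'
#' All epochs of each channel consolidated and averaged; the resulting
#' channels x samples matrix is the calibration ERP / MRCP signal.
#'
#' @param epochs an [EpochSet-class].
#' @return channels x samples matrix.
#' @export
buildErp <- function(epochs) {
  d <- epochs@data
  if (dim(d)[1] < 1) stop("need at least one trial")
  erp <- apply(d, c(2, 3), mean)
  rownames(erp) <- epochs@channels
  erp
}

#' Detection threshold from the rest portion of the calibration ERP
#'
#' mean + k * SD of the first second of the rest portion of the Cz
#' calibration ERP. The PN is a negative deflection while the rule is
#' "k SDs above the mean", so by default the series is negated first
#' (making the PN a positive peak); the same polarity convention must be
#' used at detection time.
#'
#' @param erpCz Cz row of the calibration ERP.
#' @param rate sampling rate (Hz).
#' @param k SD multiplier, one of 1, 2, 3 (other values need
#'   `allowAnyK = TRUE`).
#' @param restWindowMs rest window in ms relative to the epoch start
#'   (default the first second of the epoch, i.e. the relax phase 3-2 s
#'   before the cue).
#' @param negate operate on the negated series (default TRUE).
#' @param allowAnyK permit k outside {1,2,3}.
#' @return threshold in uV on the (possibly negated) scale.
#' @export
computeThreshold <- function(erpCz, rate, k = 2, restWindowMs = c(0, 1000),
                             negate = TRUE, allowAnyK = FALSE) {
  if (!allowAnyK && !k %in% c(1, 2, 3))
    stop("k must be 1, 2 or 3 (set allowAnyK = TRUE to override)")
  from <- msToSamples(restWindowMs[1], rate)
  to <- msToSamples(restWindowMs[2], rate) - 1L
  if (from < 0 || to >= length(erpCz)) stop("rest window not inside the epoch")
  seg <- erpCz[(from + 1L):(to + 1L)]
  if (negate) seg <- -seg
  m <- mean(seg)
  s <- if (length(seg) > 1) sd(seg) else 0
  if (is.na(s)) s <- 0
  m + k * s
}

#' Label epoch samples as rest / motor intent
#'
#' Applies a [labelingScheme()]: samples in `[ref - 500, ref + 500)` become
#' motor intent (1), samples in `[ref - 1500, ref - 500)` rest (0), all
#' others NA (unlabeled). The reference is the cue (time-based) or the
#' trial PN (PN-based).
#'
#' @param epochs an [EpochSet-class].
#' @param scheme a [labelingScheme()].
#' @param refsMs per-trial reference times in ms on the epoch's alignment
#'   axis; a scalar is recycled (e.g. cue time for time-based labeling).
#' @return the [EpochSet-class] with a label matrix attached.
#' @export
labelSamples <- function(epochs, scheme, refsMs) {
  nT <- dim(epochs@data)[1]
  nS <- dim(epochs@data)[3]
  refsMs <- rep_len(refsMs, nT)
  rate <- epochs@rate
  lab <- matrix(NA_integer_, nT, nS)
  hw <- scheme$intent_halfwidth_ms
  rd <- scheme$rest_duration_ms
  for (k in seq_len(nT)) {
    ref <- refsMs[k] - epochs@windowMs[1]        # ms from epoch start
    iFrom <- msToSamples(ref - hw, rate); iTo <- msToSamples(ref + hw, rate) - 1L
    rFrom <- msToSamples(ref - hw - rd, rate); rTo <- iFrom - 1L
    if (rFrom < 0 || iTo >= nS)
      stop(sprintf("labeling reference too close to the epoch edge in trial %d", k))
    lab[k, (rFrom + 1L):(rTo + 1L)] <- 0L
    lab[k, (iFrom + 1L):(iTo + 1L)] <- 1L
  }
  initialize(epochs, labels = lab, refsMs = as.numeric(refsMs))
}

#' Calibrate a session: PN latencies, ERP, threshold, labeled dataset
#'
#' Runs the full calibration stage on the first `nTrials` trials of a
#' session bundle. Timing quantities (per-trial PN on the virtual-Cz
#' channel, the calibration ERP, the labeled training dataset) come from
#' the zero-phase offline filter path, which has no group delay. The
#' detection threshold is computed on the causal filter path - the scale
#' the live packets arrive on. Set `trainOn = "causal"` to build the
#' labeled dataset from the causal path instead (exactly the deployment
#' representation, at the cost of its group delay against the labels).
#'
#' @param bundle a [SessionBundle-class].
#' @param nTrials number of calibration trials to use (NULL = all).
#' @param scheme a [labelingScheme()].
#' @param k threshold SD multiplier (1, 2 or 3) or "auto" for the smallest
#'   k in 1:3 with no crossings inside the calibration rest windows.
#' @param spec offline [filterSpec()]; the causal variant is derived from
#'   it.
#' @param spatial "laplacian" or "none".
#' @param trainOn filter path for the labeled dataset.
#' @return list with `calibration` (a [CalibrationResult-class]) and
#'   `dataset` (labeled [EpochSet-class] over the 1-4 s training window).
#' @export
calibrateSession <- function(bundle, nTrials = NULL,
                             scheme = labelingScheme("time_based"),
                             k = 2, spec = filterSpec(),
                             spatial = "laplacian",
                             trainOn = c("offline", "causal")) {
  trainOn <- match.arg(trainOn)
  cueMs <- bundle@plan$timeline$prep_ms %||% 3000
  causalSpec <- filterSpec(spec$low_hz, spec$high_hz, spec$order, "causal")
  pre <- lapply(bundle@recordings, preprocess, spec = spec, spatial = spatial)
  preC <- lapply(bundle@recordings, preprocess, spec = causalSpec,
                 spatial = spatial)
  calEpochs <- do.call(bindEpochs, lapply(pre, epochRecording,
                                          align = "cue",
                                          windowMs = c(-3000, 1000),
                                          cueOffsetMs = cueMs))
  calEpochsC <- do.call(bindEpochs, lapply(preC, epochRecording,
                                           align = "cue",
                                           windowMs = c(-3000, 1000),
                                           cueOffsetMs = cueMs))
  trainEpochs <- do.call(bindEpochs,
                         lapply(if (trainOn == "causal") preC else pre,
                                epochRecording, align = "prep_start",
                                windowMs = c(1000, 4000),
                                cueOffsetMs = cueMs))
  if (!is.null(nTrials)) {
    calEpochs <- subsetEpochs(calEpochs, seq_len(nTrials))
    calEpochsC <- subsetEpochs(calEpochsC, seq_len(nTrials))
    trainEpochs <- subsetEpochs(trainEpochs, seq_len(nTrials))
  }
  vcz <- virtualCz(calEpochs)
  pn <- vapply(seq_len(nrow(vcz)), function(i)
    trialPnTime(vcz[i, ], cueMs = cueMs, rate = calEpochs@rate,
                startMs = cueMs + calEpochs@windowMs[1]),
    numeric(1))
  erp <- buildErp(calEpochs)
  if (identical(k, "auto")) {
    k <- pickThresholdK(calEpochsC, cueMs)
  }
  # threshold on the causal ERP Cz: the scale the live packets arrive on
  thr <- computeThreshold(buildErp(calEpochsC)["Cz", ], calEpochsC@rate, k = k)
  refs <- if (scheme$kind == "time_based") cueMs else pn
  dataset <- labelSamples(trainEpochs, scheme, refsMs = refs)
  cal <- new("CalibrationResult", pnTimesMs = pn, avgPnMs = mean(pn),
             erp = erp,
             erpWindowMs = cueMs + calEpochs@windowMs,
             rate = calEpochs@rate,
             thresholdValue = thr, thresholdK = as.numeric(k),
             scheme = scheme$kind)
  list(calibration = cal, dataset = dataset)
}

# smallest k in 1:3 whose threshold is never crossed inside the calibration
# rest windows (batch replacement for the operator's visual choice)
pickThresholdK <- function(calEpochs, cueMs) {
  rate <- calEpochs@rate
  erpCz <- buildErp(calEpochs)["Cz", ]
  czIdx <- match("Cz", calEpochs@channels)
  restFrom <- msToSamples(-1500 - calEpochs@windowMs[1], rate)
  restTo <- msToSamples(-500 - calEpochs@windowMs[1], rate) - 1L
  for (k in 1:3) {
    thr <- computeThreshold(erpCz, rate, k = k)
    rest <- -calEpochs@data[, czIdx, (restFrom + 1L):(restTo + 1L)]
    if (!any(rest > thr)) return(k)
  }
  3
}

# concatenate epoch sets along the trial dimension
bindEpochs <- function(...) {
  sets <- list(...)
  e1 <- sets[[1]]
  if (length(sets) == 1) return(e1)
  for (e in sets[-1]) {
    stopifnot(identical(e@channels, e1@channels),
              identical(e@windowMs, e1@windowMs), e@rate == e1@rate)
  }
  datas <- lapply(sets, slot, "data")
  nT <- sum(vapply(datas, function(d) dim(d)[1], integer(1)))
  d <- dim(datas[[1]])
  out <- array(NA_real_, c(nT, d[2], d[3]))
  at <- 1L
  for (dd in datas) {
    out[at:(at + dim(dd)[1] - 1L), , ] <- dd
    at <- at + dim(dd)[1]
  }
  initialize(e1, data = out, labels = matrix(integer(), 0, 0),
             refsMs = numeric(0))
}

# restrict an epoch set to a trial subset
subsetEpochs <- function(epochs, idx) {
  lab <- if (nrow(epochs@labels)) epochs@labels[idx, , drop = FALSE]
         else epochs@labels
  refs <- if (length(epochs@refsMs)) epochs@refsMs[idx] else numeric(0)
  initialize(epochs, data = epochs@data[idx, , , drop = FALSE],
             labels = lab, refsMs = refs)
}
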