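#' @include detectors.R
NULL

#' Per-sample accuracy over labeled windows
#'
#' The ratio of correctly labeled samples to all labeled samples;
#' unlabeled samples (NA) are excluded.
#'
#' @param predictions 0/1 matrix or vector of predicted labels.
#' @param labels matching matrix/vector of true labels (NA = unlabeled).
#' @return list with `accuracy`, `correct`, `n`.
#' @export
sampleAccuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have the same length")
  keep <- !is.na(labels)
  n <- sum(keep)
  if (!n) stop("no labeled samples")
  correct <- sum(predictions[keep] == labels[keep])
  list(accuracy = correct / n, correct = correct, n = n)
}

#' Detection-error statistics against per-trial PN
#'
#' Per-trial error is `trigger_time - trial_PN_time` (ms): negative means
#' the detector fired before the PN. Reported as mean, sample SD (n-1),
#' and RMSE; fallback trials carry no detection and must be excluded by
#' the caller (their count is reported separately by [runSession()]).
#'
#' @param triggerTimesMs per-trial trigger times (ms).
#' @param pnTimesMs per-trial PN times (ms), same alignment.
#' @return list with `errors`, `mean`, `sd`, `rmse`, `n`.
#' @export
detectionError <- function(triggerTimesMs, pnTimesMs) {
  if (!length(triggerTimesMs)) stop("no trials")
  if (length(triggerTimesMs) != length(pnTimesMs))
    stop("trigger and PN vectors must have the same length")
  e <- triggerTimesMs - pnTimesMs
  list(errors = e, mean = mean(e),
       sd = if (length(e) > 1) sd(e) else 0,
       rmse = sqrt(mean(e^2)), n = length(e))
}

#' Fivefold evaluation with a fixed chronological split
#'
#' Five repetitions of the same chronological split (first 50% of trials
#' for training, the rest for testing) with distinct training seeds;
#' reports the mean and SD of held-out per-sample accuracy. For a
#' deterministic trainer the SD is zero.
#'
#' @param dataset a labeled, chronologically ordered [EpochSet-class].
#' @param trainer function(trainSet, seed) returning a per-sample detector.
#' @param seeds five training seeds.
#' @param split training fraction (0.5).
#' @return list with `fold` (per-fold accuracies), `mean`, `sd`.
#' @export
fivefoldEval <- function(dataset, trainer, seeds = 1:5, split = 0.5) {
  n <- nTrials(dataset)
  if (n < 2) stop("need at least two trials")
  nTrain <- floor(n * split)
  trainSet <- subsetEpochs(dataset, seq_len(nTrain))
  testSet <- subsetEpochs(dataset, (nTrain + 1):n)
  acc <- vapply(seeds, function(s) {
    model <- trainer(trainSet, s)
    heldOutAccuracy(model, testSet)
  }, numeric(1))
  list(fold = acc, mean = mean(acc), sd = sd(acc))
}

#' Two-sample t test on detection accuracies
#'
#' Standard two-sample t statistic (pooled variance) with a two-sided
#' p-value, as used to compare mean accuracies between detectors.
#'
#' @param a,b accuracy vectors (each of length >= 2).
#' @return list with `t`, `p`, `df`.
#' @export
twoSampleTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each arm needs >= 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1,
                                        df = length(a) + length(b) - 2))
    stop("degenerate variance in both arms")
  }
  ht <- t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

# mean band power via the average periodogram across epochs and channels;
# x is trials x samples (single channel) or trials x channels x samples
bandPower <- function(x, rate, bandHz) {
  if (length(dim(x)) == 3)
    return(mean(apply(x, 2, bandPower, rate = rate, bandHz = bandHz)))
  n <- ncol(x)
  f <- (seq_len(n) - 1) * rate / n
  keep <- f >= bandHz[1] & f <= bandHz[2]
  if (!any(keep)) stop("band contains no frequency bins")
  pw <- apply(x, 1, function(tr) {
    tr <- tr - mean(tr)
    Mod(fft(tr))^2 / n
  })                                  # bins x trials
  mean(colMeans(t(pw)[, keep, drop = FALSE]))
}

#' Event-related desynchronization (ERD)
#'
#' Band-power reduction from rest during movement,
#' `10 log10(P_rest / P_move)` dB averaged over the channel set; positive
#' values mean desynchronization. Band power is the mean periodogram power
#' in the band across epochs (mean-detrended, no taper).
#'
#' @param moveEpochs,restEpochs [EpochSet-class] objects (movement /
#'   baseline), same channels and rate.
#' @param band "alpha" (8-12 Hz), "beta" (13-30 Hz) or a numeric pair.
#' @param channels channel subset (default: all shared channels).
#' @return ERD in dB.
#' @export
erd <- function(moveEpochs, restEpochs, band = c("alpha", "beta"),
                channels = NULL) {
  bandHz <- if (is.numeric(band)) band
            else switch(match.arg(band), alpha = c(8, 12), beta = c(13, 30))
  pick <- function(e) {
    idx <- if (is.null(channels)) seq_along(e@channels)
           else match(channels, e@channels)
    if (anyNA(idx)) stop("missing channel(s)")
    e@data[, idx, , drop = FALSE]
  }
  pMove <- bandPower(pick(moveEpochs), moveEpochs@rate, bandHz)
  pRest <- bandPower(pick(restEpochs), restEpochs@rate, bandHz)
  if (pMove <= 0 || pRest <= 0) stop("zero band power")
  10 * log10(pRest / pMove)
}

#' Laterality index of ERD
#'
#' `(ERD_contra - ERD_ipsi) / (ERD_contra + ERD_ipsi)`; lies in `[-1, 1]`
#' when both ERDs are non-negative.
#'
#' @param erdContra ERD on the hemisphere contralateral to the trained side.
#' @param erdIpsi ERD on the ipsilateral hemisphere.
#' @export
lateralityIndex <- function(erdContra, erdIpsi) {
  den <- erdContra + erdIpsi
  if (den == 0) stop("zero denominator")
  (erdContra - erdIpsi) / den
}
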