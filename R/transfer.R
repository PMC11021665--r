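#' @include detectors.R
NULL

#' Fit per-channel z-normalization from calibration epochs
#'
#' Input normalization used by the transfer scheme to counter
#' session-to-session drift of the feature space: each channel is scaled
#' by subtracting its mean and dividing by its SD, both estimated from the
#' session's calibration trials. The state is fitted once and applied
#' explicitly; it is never silently refitted.
#'
#' @param epochs an [EpochSet-class] of calibration trials.
#' @return list with per-channel `mean` and `sd` (a NormState).
#' @export
fitNorm <- function(epochs) {
  d <- epochs@data
  if (!dim(d)[1]) stop("no calibration data")
  m <- apply(d, 2, mean)
  s <- apply(d, 2, sd)
  if (any(s <= 0 | !is.finite(s)))
    stop("zero-variance channel(s): ",
         paste(epochs@channels[s <= 0 | !is.finite(s)], collapse = ", "))
  list(mean = m, sd = s, channels = epochs@channels)
}

#' Apply a normalization state
#'
#' @param norm a NormState from [fitNorm()].
#' @param x an [EpochSet-class] or a channels x samples matrix.
#' @return the normalized object.
#' @export
applyNorm <- function(norm, x) {
  if (is(x, "EpochSet")) {
    d <- sweep(sweep(x@data, 2, norm$mean, "-"), 2, norm$sd, "/")
    return(initialize(x, data = d))
  }
  sweep(sweep(x, 1, norm$mean, "-"), 1, norm$sd, "/")
}

#' Transfer specification
#'
#' @param finetune_trials calibration trials of the new session used for
#'   fine-tuning (25 by default).
#' @param hidden units of the newly inserted bidirectional layer.
#' @param epochs,batch,lr,beta1,beta2,grad_clip fine-tuning hyperparameters
#'   (defaults mirror base training).
#' @param seed fine-tuning seed.
#' @export
transferSpec <- function(finetune_trials = 25, hidden = 100, epochs = 100,
                         batch = 8, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         grad_clip = 1, seed = 1) {
  list(finetune_trials = finetune_trials, hidden = hidden, epochs = epochs,
       batch = batch, lr = lr, beta1 = beta1, beta2 = beta2,
       grad_clip = grad_clip, seed = seed)
}

#' Transfer a trained LSTM to a new session
#'
#' The previous session's input stage and bidirectional LSTM layer are
#' frozen; a fresh bidirectional layer (and a new softmax readout) is
#' inserted on top and trained on the first `finetune_trials` labeled
#' trials of the new session, z-normalized with the new session's own
#' statistics. The frozen weights are byte-identical to the previous
#' model's after fine-tuning.
#'
#' @param prev a base (non-transferred) [LSTMDetector-class].
#' @param dataset labeled [EpochSet-class] of the new session's calibration
#'   trials (at least `finetune_trials` of them; the first
#'   `finetune_trials` are used).
#' @param spec a [transferSpec()].
#' @param norm normalization state for the new session; fitted from the
#'   fine-tuning trials by default.
#' @return a transferred [LSTMDetector-class].
#' @export
transferModel <- function(prev, dataset, spec = transferSpec(), norm = NULL) {
  if (!is(prev, "LSTMDetector")) stop("transfer requires an LSTM model")
  if (length(prev@frozen)) stop("chained transfer of a transferred model is not supported")
  checkLabeled(dataset)
  if (nTrials(dataset) < spec$finetune_trials)
    stop(sprintf("need %d fine-tuning trials, have %d",
                 spec$finetune_trials, nTrials(dataset)))
  dataset <- subsetEpochs(dataset, seq_len(spec$finetune_trials))
  inp <- buildDetectorInput(dataset, length(prev@channels))
  if (is.null(norm)) {
    norm <- list(mean = apply(aperm(inp$cube, c(2, 1, 3)), 2, mean),
                 sd = apply(aperm(inp$cube, c(2, 1, 3)), 2, sd),
                 channels = inp$channels)
    if (any(norm$sd <= 0)) stop("zero-variance channel in fine-tuning data")
  }
  X <- normalizeCube(inp$cube, norm)
  Y <- t(dataset@labels)
  Y[is.na(Y)] <- -1L
  storage.mode(Y) <- "integer"
  # packet-length tiles, frozen-layer features computed per tile exactly as
  # the real-time path will compute them
  tiles <- tileCube(X, prev@config$seq_len, Y)
  feats <- .cpp_bilstm_hidden(prev@params, tiles$X)
  init <- .cpp_bilstm_init(dim(feats)[1], spec$hidden, spec$seed)
  fit <- .cpp_bilstm_train(feats, tiles$Y, init, as.integer(spec$epochs),
                           as.integer(spec$batch), as.integer(spec$seed),
                           spec$lr, spec$beta1, spec$beta2, spec$grad_clip,
                           FALSE)
  cfg <- prev@config
  cfg$hidden <- spec$hidden
  new("LSTMDetector", channels = prev@channels, seed = as.numeric(spec$seed),
      params = fit$params, config = cfg, norm = norm,
      history = as.numeric(fit$loss), frozen = prev@params)
}

#' Compare transferred vs freshly trained models across sessions
#'
#' For each session after the first: train a base model on the previous
#' session's trials, transfer it using the first `finetune_trials` trials
#' of the current session, and compare its held-out sample accuracy with a
#' fresh model trained on the current session's first `freshTrials` trials.
#' Held-out accuracy is evaluated on the current session's remaining
#' trials in both arms.
#'
#' @param datasets list of labeled [EpochSet-class], one per session,
#'   chronologically ordered.
#' @param baseConfig [lstmConfig()] for the base/fresh models.
#' @param spec a [transferSpec()].
#' @param freshTrials trials for the non-transferred arm (50 by default).
#' @param evalFrom first trial index of the held-out span (defaults to
#'   after the fresh-training span).
#' @return data.frame with one row per compared session: `session`,
#'   `transferred`, `fresh` (held-out sample accuracies in percent).
#' @export
compareTransfer <- function(datasets, baseConfig = lstmConfig(),
                            spec = transferSpec(), freshTrials = 50,
                            evalFrom = freshTrials + 1) {
  if (length(datasets) < 2) stop("need at least two sessions")
  out <- NULL
  for (s in 2:length(datasets)) {
    prevSet <- datasets[[s - 1]]
    curSet <- datasets[[s]]
    normPrev <- fitNorm(prevSet)
    base <- trainLSTM(prevSet, baseConfig, norm = normPrev)
    transferred <- transferModel(base, curSet, spec)
    fresh <- trainLSTM(subsetEpochs(curSet, seq_len(freshTrials)), baseConfig)
    held <- subsetEpochs(curSet, evalFrom:nTrials(curSet))
    out <- rbind(out, data.frame(
      session = s,
      transferred = 100 * heldOutAccuracy(transferred, held),
      fresh = 100 * heldOutAccuracy(fresh, held)))
  }
  out
}
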