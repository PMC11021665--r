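#' @include calibration.R
NULL

#' LSTM detector configuration
#'
#' A bidirectional LSTM layer (100 units by default) followed by a dense
#' layer and per-time-step 2-class softmax; trained with Adam for 100
#' epochs. `input_dim` selects the input representation: 20 (the
#' sensorimotor channels, the default), 21 (the 20 channels plus the
#' virtual-Cz average as an extra input), or 64 (the full montage).
#'
#' @param input_dim 20, 21, or 64.
#' @param hidden LSTM units per direction.
#' @param epochs training epochs.
#' @param batch minibatch size (sequences per optimizer step); unspecified
#'   upstream, mirrors the MLP's batch of 8.
#' @param seq_len training/evaluation sequence length in samples. Epochs
#'   are tiled into windows of this length, the same packet shape the
#'   real-time loop classifies; this also prevents the degenerate solution
#'   of labeling by absolute epoch position, which cannot transfer to
#'   packet classification.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param seed training seed (weight init and batch shuffling).
#' @export
lstmConfig <- function(input_dim = 20, hidden = 100, epochs = 100,
                       batch = 8, seq_len = 25, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, grad_clip = 1, seed = 1) {
  stopifnot(hidden > 0, epochs >= 1, batch >= 1, seq_len >= 2,
            input_dim %in% c(20, 21, 64))
  list(kind = "lstm", input_dim = input_dim, hidden = hidden,
       epochs = epochs, batch = batch, seq_len = seq_len, lr = lr,
       beta1 = beta1, beta2 = beta2, grad_clip = grad_clip, seed = seed)
}

#' MLP detector configuration
#'
#' Per-sample classification of the instantaneous channel vector with a
#' ReLU multilayer perceptron; three hidden layers of width 20, SGD with
#' learning rate 0.01 and batch size 8.
#'
#' @param hidden hidden-layer widths (use `c(20, 20)` for the two-layer
#'   variant).
#' @param epochs training epochs.
#' @param batch minibatch size.
#' @param lr SGD learning rate.
#' @param seed training seed.
#' @export
mlpConfig <- function(hidden = c(20, 20, 20), epochs = 50, batch = 8,
                      lr = 0.01, seed = 1) {
  stopifnot(length(hidden) >= 1, all(hidden > 0))
  list(kind = "mlp", hidden = hidden, epochs = epochs, batch = batch,
       lr = lr, seed = seed)
}

# epochs -> (D x N x T) cube in the detector's input representation
buildDetectorInput <- function(epochs, input_dim = length(epochs@channels)) {
  d <- epochs@data
  channels <- epochs@channels
  if (input_dim == 21 && !"VCz" %in% channels) {
    vcz <- virtualCz(epochs)                     # trials x samples
    d2 <- array(NA_real_, dim = dim(d) + c(0, 1, 0))
    d2[, seq_along(channels), ] <- d
    d2[, length(channels) + 1, ] <- vcz
    d <- d2
    channels <- c(channels, "VCz")
  }
  if (dim(d)[2] != input_dim)
    stop(sprintf("dataset has %d channels but the detector expects %d",
                 dim(d)[2], input_dim))
  list(cube = aperm(d, c(2, 1, 3)), channels = channels)
}

checkLabeled <- function(epochs) {
  if (!nrow(epochs@labels))
    stop("dataset is unlabeled; run labelSamples() first")
  present <- unique(epochs@labels[!is.na(epochs@labels)])
  if (length(present) < 2)
    stop("training data must contain both classes (rest and motor intent)")
}

# per-channel z-normalization applied to a cube
normalizeCube <- function(x, norm) {
  if (!length(norm)) return(x)
  sweep(sweep(x, 1, norm$mean, "-"), 1, norm$sd, "/")
}

# Tile sequences (D x N x T) into windows of `len` along time:
# returns X (D x M x len) and Y (len x M); windows without any labeled
# sample are dropped when labels are supplied. A trailing remainder
# shorter than `len` is dropped (training) - predictStitched() covers it.
tileCube <- function(X, len, Y = NULL) {
  d <- dim(X)
  nWin <- d[3] %/% len
  if (nWin < 1) stop("sequences shorter than seq_len")
  idx <- lapply(seq_len(nWin), function(w) ((w - 1) * len + 1):(w * len))
  Xw <- array(NA_real_, c(d[1], d[2] * nWin, len))
  Yw <- if (!is.null(Y)) matrix(NA_integer_, len, d[2] * nWin)
  at <- 1L
  for (w in seq_len(nWin)) {
    Xw[, at:(at + d[2] - 1L), ] <- X[, , idx[[w]], drop = FALSE]
    if (!is.null(Y)) Yw[, at:(at + d[2] - 1L)] <- Y[idx[[w]], , drop = FALSE]
    at <- at + d[2]
  }
  if (!is.null(Y)) {
    keep <- colSums(Yw >= 0, na.rm = TRUE) > 0
    Xw <- Xw[, keep, , drop = FALSE]
    Yw <- Yw[, keep, drop = FALSE]
  }
  list(X = Xw, Y = Yw, nWin = nWin)
}

#' Train the bidirectional LSTM sequence labeler
#'
#' @param dataset a labeled [EpochSet-class] (see [labelSamples()]).
#' @param config an [lstmConfig()].
#' @param norm optional normalization state from [fitNorm()]; applied to
#'   the inputs and stored in the model.
#' @return an [LSTMDetector-class]; training is deterministic given the
#'   config seed, and the per-epoch loss history is retained.
#' @export
trainLSTM <- function(dataset, config = lstmConfig(), norm = list()) {
  checkLabeled(dataset)
  inp <- buildDetectorInput(dataset, config$input_dim)
  X <- normalizeCube(inp$cube, norm)
  Y <- t(dataset@labels)                          # T x N
  Y[is.na(Y)] <- -1L
  storage.mode(Y) <- "integer"
  tiles <- tileCube(X, config$seq_len, Y)
  init <- .cpp_bilstm_init(config$input_dim, config$hidden, config$seed)
  fit <- .cpp_bilstm_train(tiles$X, tiles$Y, init, as.integer(config$epochs),
                           as.integer(config$batch), as.integer(config$seed),
                           config$lr, config$beta1, config$beta2,
                           config$grad_clip, FALSE)
  new("LSTMDetector", channels = inp$channels, seed = as.numeric(config$seed),
      params = fit$params, config = config, norm = norm,
      history = as.numeric(fit$loss), frozen = list())
}

#' Train the MLP per-sample classifier
#'
#' @param dataset a labeled [EpochSet-class].
#' @param config an [mlpConfig()].
#' @param norm optional normalization state from [fitNorm()].
#' @return an [MLPDetector-class].
#' @export
trainMLP <- function(dataset, config = mlpConfig(), norm = list()) {
  checkLabeled(dataset)
  inp <- buildDetectorInput(dataset)
  X <- normalizeCube(inp$cube, norm)
  lab <- t(dataset@labels)                        # T x N
  flat <- matrix(aperm(X, c(1, 3, 2)), nrow = dim(X)[1])   # D x (T*N)
  labv <- as.integer(lab)                                   # column-major T*N
  keep <- !is.na(labv)
  Xl <- flat[, keep, drop = FALSE]
  yl <- labv[keep]
  if (length(unique(yl)) < 2)
    stop("training data must contain both classes (rest and motor intent)")
  init <- .cpp_mlp_init(nrow(Xl), as.integer(config$hidden), config$seed)
  fit <- .cpp_mlp_train(Xl, yl, init, as.integer(config$epochs),
                        as.integer(config$batch), as.integer(config$seed),
                        config$lr)
  new("MLPDetector", channels = inp$channels, seed = as.numeric(config$seed),
      params = fit$params, config = config, norm = norm,
      history = as.numeric(fit$loss))
}

# class-1 probability per sample for a cube in model representation
modelProb <- function(model, X) {
  X <- normalizeCube(X, model@norm)
  if (is(model, "LSTMDetector")) {
    len <- model@config$seq_len %||% dim(X)[3]
    lstmOne <- function(Xw) {
      if (length(model@frozen)) Xw <- .cpp_bilstm_hidden(model@frozen, Xw)
      .cpp_bilstm_prob(model@params, Xw)                 # T x N
    }
    d <- dim(X)
    if (d[3] <= len) return(lstmOne(X))
    # tile into packet-length windows and stitch the probabilities back
    out <- matrix(NA_real_, d[3], d[2])
    nWin <- d[3] %/% len
    tiles <- tileCube(X, len)
    p <- lstmOne(tiles$X)                                # len x (N*nWin)
    for (w in seq_len(nWin)) {
      cols <- ((w - 1) * d[2] + 1):(w * d[2])
      out[((w - 1) * len + 1):(w * len), ] <- p[, cols]
    }
    rem <- d[3] - nWin * len
    if (rem > 0) {                                       # trailing remainder
      tailX <- X[, , (d[3] - len + 1):d[3], drop = FALSE]
      pt <- lstmOne(tailX)
      out[(nWin * len + 1):d[3], ] <- pt[(len - rem + 1):len, , drop = FALSE]
    }
    out
  } else if (is(model, "MLPDetector")) {
    d <- dim(X)
    flat <- matrix(aperm(X, c(1, 3, 2)), nrow = d[1])    # D x (T*N)
    matrix(.cpp_mlp_prob(model@params, flat), nrow = d[3])  # T x N
  } else stop("not a per-sample classifier")
}

#' Per-sample predictions for an epoch set
#'
#' @param model a trained [MLPDetector-class] or [LSTMDetector-class].
#' @param epochs an [EpochSet-class] in the model's channel space.
#' @return integer trials x samples matrix of 0/1 labels.
#' @export
predictSamples <- function(model, epochs) {
  inp <- buildDetectorInput(epochs, length(model@channels))
  p <- modelProb(model, inp$cube)
  t(p >= 0.5) * 1L
}

#' Held-out per-sample accuracy of a detector on a labeled epoch set
#'
#' @param model a trained per-sample detector.
#' @param epochs a labeled [EpochSet-class].
#' @return accuracy in `[0, 1]` over the labeled samples.
#' @export
heldOutAccuracy <- function(model, epochs) {
  checkLabeled(epochs)
  pred <- predictSamples(model, epochs)
  sampleAccuracy(pred, epochs@labels)$accuracy
}

#' @rdname classifyPacket
#' @export
setMethod("classifyPacket", "LSTMDetector", function(model, packet) {
  packetDecisionFor(model, packet)
})

#' @rdname classifyPacket
#' @export
setMethod("classifyPacket", "MLPDetector", function(model, packet) {
  packetDecisionFor(model, packet)
})

packetDecisionFor <- function(model, packet) {
  if (!is.matrix(packet)) packet <- matrix(packet, nrow = 1)
  if (nrow(packet) != length(model@channels))
    stop(sprintf("packet has %d channels but the model expects %d (%s)",
                 nrow(packet), length(model@channels),
                 paste(model@channels, collapse = ",")))
  X <- array(packet, dim = c(nrow(packet), 1, ncol(packet)))
  p <- modelProb(model, X)
  labels <- as.integer(p[, 1] >= 0.5)
  list(labels = labels, positive_count = sum(labels),
       length = length(labels))
}

#' Construct a threshold detector
#'
#' @param threshold threshold in uV on the polarity-adjusted scale (from
#'   [computeThreshold()]).
#' @param k the SD multiplier it came from.
#' @param channel the channel the rule watches (Cz).
#' @param negatePolarity whether packets are negated before comparison
#'   (must match how the threshold was computed).
#' @export
thresholdDetector <- function(threshold, k = NA_real_, channel = "Cz",
                              negatePolarity = TRUE) {
  new("ThresholdDetector", channels = channel, seed = NA_real_,
      threshold = threshold, k = as.numeric(k),
      negatePolarity = negatePolarity)
}

#' Construct an average-PN (open-loop) detector
#'
#' @param avgPnMs mean calibration PN latency, ms after preparation start.
#' @export
averagePnDetector <- function(avgPnMs) {
  new("AveragePNDetector", channels = character(0), seed = NA_real_,
      avgPnMs = avgPnMs)
}

#' Threshold trigger rule
#'
#' Fires iff the packet mean strictly exceeds the threshold (both on the
#' polarity-adjusted scale).
#'
#' @param packet numeric series (the Cz packet, already polarity-adjusted).
#' @param threshold threshold in uV.
#' @export
thresholdDecision <- function(packet, threshold) {
  if (!length(packet)) stop("empty packet")
  mean(packet) > threshold
}

#' Average-PN trigger rule
#'
#' Fires on the first timer tick at or after the average PN time.
#'
#' @param elapsedMs elapsed time since preparation start (ms).
#' @param avgPnMs the average calibration PN latency (ms).
#' @export
averagePnDecision <- function(elapsedMs, avgPnMs) {
  elapsedMs >= avgPnMs
}

#' Save / load a detector model
#'
#' Serialization preserves behavior exactly: a reloaded model produces
#' identical decisions on any input.
#'
#' @param model a [DetectorModel-class].
#' @param path file path.
#' @export
saveDetector <- function(model, path) {
  stopifnot(is(model, "DetectorModel"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname saveDetector
#' @export
readDetector <- function(path) {
  x <- readRDS(path)
  if (!is(x, "DetectorModel")) stop("file does not hold a detector model")
  x
}
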