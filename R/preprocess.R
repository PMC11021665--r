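#' @include recording.R
NULL

#' Band-pass filter specification for the MRCP band
#'
#' The MRCP lives below 10 Hz; the chain retains 0.05-10 Hz. The filter is
#' realized as a cascade of Butterworth high-pass and low-pass sections.
#' Offline ("offline_zero_phase") filtering is forward-backward and
#' introduces no group delay; the real-time path ("causal") is
#' forward-only, as a live system can only be.
#'
#' @param low_hz high-pass edge (Hz).
#' @param high_hz low-pass edge (Hz).
#' @param order Butterworth order of each section.
#' @param mode "offline_zero_phase" or "causal".
#' @export
filterSpec <- function(low_hz = 0.05, high_hz = 10, order = 2,
                       mode = c("offline_zero_phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 1)
  list(low_hz = low_hz, high_hz = high_hz, order = order, mode = mode)
}

# filter one matrix (channels x samples) with the cascade
applyBandpass <- function(data, rate, spec) {
  if (spec$high_hz >= rate / 2)
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g)",
                 spec$high_hz, rate / 2))
  hp <- signal::butter(spec$order, spec$low_hz / (rate / 2), type = "high")
  lp <- signal::butter(spec$order, spec$high_hz / (rate / 2), type = "low")
  # The high-pass edge transients have a ~1/low_hz time constant, so both
  # paths are constant-padded: the offline path on both ends (filtfilt
  # itself does no padding), the causal path on the left only - a live
  # system would be streaming long before detection starts, which the
  # padding emulates by bringing the filter state to steady state.
  padLen <- ceiling(3 / spec$low_hz * rate)
  run <- function(x) {
    if (spec$mode == "offline_zero_phase") {
      n <- length(x)
      xp <- c(rep(x[1], padLen), x, rep(x[n], padLen))
      xp <- signal::filtfilt(hp, xp)
      xp <- signal::filtfilt(lp, xp)
      xp[(padLen + 1):(padLen + n)]
    } else {
      # each section is applied twice forward, so the causal magnitude
      # response equals the zero-phase chain's; the residual difference
      # between the two paths is pure (causal) phase delay
      xp <- c(rep(x[1], padLen), x)
      xp <- as.numeric(signal::filter(hp, xp))
      xp <- as.numeric(signal::filter(hp, xp))
      xp <- as.numeric(signal::filter(lp, xp))
      xp <- as.numeric(signal::filter(lp, xp))
      xp[(padLen + 1):length(xp)]
    }
  }
  out <- t(apply(data, 1, run))
  dimnames(out) <- dimnames(data)
  out
}

#' Band-pass filter a recording into the MRCP band
#'
#' @param recording an [EEGRecording-class].
#' @param spec a [filterSpec()].
#' @return a filtered [EEGRecording-class]; shape, montage and triggers are
#'   unchanged.
#' @export
bandpass <- function(recording, spec = filterSpec()) {
  new("EEGRecording",
      data = applyBandpass(recording@data, recording@rate, spec),
      rate = recording@rate, montage = recording@montage,
      events = recording@events)
}

#' Restrict a recording to the 20 sensorimotor channels
#'
#' Output channel order is the canonical sensorimotor order
#' ([sensorimotorChannels()]) regardless of input order.
#'
#' @param recording an [EEGRecording-class].
#' @param channels channel list override.
#' @export
selectSensorimotor <- function(recording, channels = sensorimotorChannels()) {
  missing <- setdiff(channels, recording@montage@labels)
  if (length(missing))
    stop("missing sensorimotor channel(s): ", paste(missing, collapse = ", "))
  data <- recording@data[channels, , drop = FALSE]
  m <- validateMontage(channels)
  new("EEGRecording", data = data, rate = recording@rate, montage = m,
      events = recording@events)
}

#' Surface Laplacian spatial filter
#'
#' Each channel minus the mean of its montage neighbors; sharpens focal
#' sources and cancels spatially uniform activity. Linear; shape preserved.
#'
#' @param recording an [EEGRecording-class].
#' @param montage montage providing the neighbor map (defaults to the
#'   recording's own).
#' @export
laplacian <- function(recording, montage = NULL) {
  if (is.null(montage)) montage <- recording@montage
  data <- recording@data
  out <- data
  for (ch in rownames(data)) {
    nb <- montage@neighbors[[ch]]
    nb <- nb[nb %in% rownames(data)]
    if (!length(nb))
      stop("channel has no neighbors for the Laplacian: ", ch)
    out[ch, ] <- data[ch, ] -
      colMeans(data[nb, , drop = FALSE])
  }
  new("EEGRecording", data = out, rate = recording@rate,
      montage = recording@montage, events = recording@events)
}

#' Virtual Cz channel
#'
#' Per-sample arithmetic mean of channels C1, C3 and Cz, located medially
#' and centrally above the motor cortex; used to localize the trial PN for
#' calibration and error analysis.
#'
#' @param x an [EEGRecording-class] (returns a numeric series) or an
#'   [EpochSet-class] (returns a trials x samples matrix).
#' @param channels the channels averaged.
#' @export
setGeneric("virtualCz", function(x, channels = c("C1", "C3", "Cz"))
  standardGeneric("virtualCz"))

#' @rdname virtualCz
#' @export
setMethod("virtualCz", "EEGRecording", function(x, channels) {
  missing <- setdiff(channels, rownames(x@data))
  if (length(missing)) stop("missing channel(s): ", paste(missing, collapse = ", "))
  colMeans(x@data[channels, , drop = FALSE])
})

#' @rdname virtualCz
#' @export
setMethod("virtualCz", "EpochSet", function(x, channels) {
  idx <- match(channels, x@channels)
  if (anyNA(idx)) stop("missing channel(s): ",
                       paste(channels[is.na(idx)], collapse = ", "))
  out <- apply(x@data[, idx, , drop = FALSE], c(1, 3), mean)
  matrix(out, nrow = dim(x@data)[1])
})

#' Epoch a recording around its trials
#'
#' One epoch per trial, aligned to the preparation start (trigger 6) or to
#' the cue to move (preparation start + 3000 ms). The window is half-open
#' `[start, end)` in ms; sample count is `floor((end - start) * rate / 1000)`.
#'
#' @param recording an [EEGRecording-class] with protocol triggers.
#' @param align "prep_start" or "cue".
#' @param windowMs length-2 numeric window in ms relative to the alignment.
#' @param cueOffsetMs cue time relative to preparation start.
#' @return an [EpochSet-class].
#' @export
epochRecording <- function(recording, align = c("prep_start", "cue"),
                           windowMs = c(-3000, 1000), cueOffsetMs = 3000) {
  align <- match.arg(align)
  trials <- extractTrials(recording)
  rate <- recording@rate
  nWin <- msToSamples(windowMs[2] - windowMs[1], rate)
  nT <- nrow(trials)
  out <- array(NA_real_, dim = c(nT, nrow(recording@data), nWin))
  for (k in seq_len(nT)) {
    anchor <- trials$prep[k] +
      if (align == "cue") msToSamples(cueOffsetMs, rate) else 0L
    from <- anchor + msToSamples(windowMs[1], rate)
    to <- from + nWin - 1L
    if (from < 0 || to >= ncol(recording@data))
      stop(sprintf("epoch window exceeds recording bounds for trial %d", k))
    out[k, , ] <- recording@data[, (from + 1L):(to + 1L)]
  }
  new("EpochSet", data = out, rate = rate,
      channels = recording@montage@labels,
      windowMs = as.numeric(windowMs), align = align,
      labels = matrix(integer(), 0, 0), refsMs = numeric(0))
}

#' Standard offline preprocessing chain
#'
#' Band-pass to the MRCP band, surface Laplacian over the full montage,
#' then restriction to the 20 sensorimotor channels - the representation
#' every detector trains and runs on.
#'
#' @param recording an [EEGRecording-class].
#' @param spec a [filterSpec()]; use `mode = "causal"` for the real-time
#'   path.
#' @param spatial "laplacian" or "none".
#' @param channels sensorimotor channel list.
#' @export
preprocess <- function(recording, spec = filterSpec(),
                       spatial = c("laplacian", "none"),
                       channels = sensorimotorChannels()) {
  spatial <- match.arg(spatial)
  r <- bandpass(recording, spec)
  if (spatial == "laplacian") r <- laplacian(r)
  selectSensorimotor(r, channels)
}
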