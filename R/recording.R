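#' @include AllClasses.R montage.R
NULL

#' Construct an EEG recording
#'
#' @param data numeric matrix channels x samples, amplitudes in uV.
#' @param rate sampling rate (Hz).
#' @param montage a [Montage-class] or NULL to build one from `labels`.
#' @param events data.frame with integer columns `code`, `sample` (0-based).
#' @param labels channel labels when `montage` is NULL; defaults to the
#'   rownames of `data`.
#' @return an [EEGRecording-class].
#' @export
eegRecording <- function(data, rate, montage = NULL,
                         events = data.frame(code = integer(), sample = integer()),
                         labels = rownames(data)) {
  if (is.null(montage)) {
    if (is.null(labels)) stop("channel labels required")
    montage <- validateMontage(labels)
  }
  rownames(data) <- montage@labels
  events <- data.frame(code = as.integer(events$code),
                       sample = as.integer(events$sample))
  events <- events[order(events$sample, events$code), , drop = FALSE]
  rownames(events) <- NULL
  new("EEGRecording", data = data, rate = as.numeric(rate),
      montage = montage, events = events)
}

#' Construct a session bundle
#'
#' @param recordings list of [EEGRecording-class], one per block.
#' @param sessionId character identifier.
#' @param groundTruth optional data.frame (`block`, `trial`, `pn_ms`,
#'   `amplitude`).
#' @param plan the generating session plan, if any.
#' @return a [SessionBundle-class].
#' @export
sessionBundle <- function(recordings, sessionId = "session",
                          groundTruth = NULL, plan = list()) {
  if (is(recordings, "EEGRecording")) recordings <- list(recordings)
  if (is.null(groundTruth))
    groundTruth <- data.frame(block = integer(), trial = integer(),
                              pn_ms = numeric(), amplitude = numeric())
  new("SessionBundle", recordings = recordings,
      sessionId = as.character(sessionId),
      groundTruth = groundTruth, plan = plan)
}

#' Write / read the internal single-file bundle
#'
#' The internal bundle is a single-file serialization of the container
#' object (R's native format, version 3). Write-then-read is the identity
#' on data, rate, labels, and triggers.
#'
#' @param x an [EEGRecording-class] or [SessionBundle-class].
#' @param path file path (conventionally `.rds`).
#' @return `writeBundle` returns `path` invisibly; `readBundle` returns the
#'   stored object.
#' @export
writeBundle <- function(x, path) {
  stopifnot(is(x, "EEGRecording") || is(x, "SessionBundle"))
  saveRDS(x, path, version = 3)
  invisible(path)
}

#' @rdname writeBundle
#' @export
readBundle <- function(path) {
  x <- readRDS(path)
  if (!(is(x, "EEGRecording") || is(x, "SessionBundle")))
    stop("file is not an mrcpbci bundle: ", path)
  x
}

#' Export trigger events as CSV
#'
#' Columns: `code`, `sample` (0-based), `time_s`.
#'
#' @param recording an [EEGRecording-class].
#' @param path output file.
#' @export
exportEvents <- function(recording, path) {
  ev <- recording@events
  ev$time_s <- ev$sample / recording@rate
  write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' Extract trial slices from the trigger stream
#'
#' Each trial starts at a code-8 event; its preparation phase starts at the
#' first code-6 event that follows (the real-time clock zero); the slice
#' ends at the next code-8 event, at a closing code-7 event, or at the end
#' of the recording. Non-protocol codes are ignored. A code-8 event with no
#' following code-6 is a malformed trial.
#'
#' @param recording an [EEGRecording-class].
#' @return data.frame with 0-based sample columns `trial`, `start`, `prep`,
#'   `end` (half-open); zero rows if there are no code-8 events.
#' @examples
#' m <- validateMontage(c("Cz", "C1"))
#' ev <- data.frame(code = c(8, 6, 8, 6, 7), sample = c(0, 10, 100, 110, 190))
#' r <- eegRecording(matrix(0, 2, 200, dimnames = list(channelNames(m), NULL)),
#'                   500, m, ev)
#' extractTrials(r)
#' @export
extractTrials <- function(recording) {
  ev <- recording@events
  ev <- ev[ev$code %in% c(TRIG_TRIAL_START, TRIG_PREP_START, TRIG_BLOCK_END), ,
           drop = FALSE]
  starts <- which(ev$code == TRIG_TRIAL_START)
  out <- data.frame(trial = integer(), start = integer(), prep = integer(),
                    end = integer())
  if (!length(starts)) return(out)
  nSamp <- ncol(recording@data)
  for (k in seq_along(starts)) {
    i <- starts[k]
    nxt <- if (k < length(starts)) starts[k + 1] else nrow(ev) + 1L
    between <- ev[seq_len(nrow(ev)) > i & seq_len(nrow(ev)) < nxt, , drop = FALSE]
    prep <- between$sample[between$code == TRIG_PREP_START][1]
    if (is.na(prep))
      stop(sprintf("malformed trial %d: trial start (code 8) without a following prep start (code 6)", k))
    endCand <- c(between$sample[between$code == TRIG_BLOCK_END],
                 if (k < length(starts)) ev$sample[starts[k + 1]], nSamp)
    out <- rbind(out, data.frame(trial = k, start = ev$sample[i],
                                 prep = prep, end = min(endCand)))
  }
  out
}
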