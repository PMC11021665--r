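#' @include detectors.R
NULL

#' Real-time harness specification
#'
#' Deterministic re-creation of the live loop: a timer tick every 50 ms
#' classifies the most recent packet of samples; time zero is the
#' preparation-start trigger (code 6). Detection is eligible from
#' `detection_start_ms`; a trigger inside the rest window
#' `[1500, 2500)` ms is a false positive, inside the PN window
#' `[2500, 3500]` ms a true positive; if nothing fired by `fallback_ms`
#' an automatic fallback trigger is issued (when enabled). Windows are
#' expressed in ms so the bookkeeping is packet-length independent.
#'
#' @param tick_ms timer period.
#' @param packet_len_samples samples per packet (25 by default; 50 for the
#'   100 ms-packet variant).
#' @param trigger_fraction fraction of packet samples that must be labeled
#'   motor intent to fire (0.8).
#' @param detection_start_ms first eligible decision timestamp.
#' @param rest_window_ms half-open rest window.
#' @param pn_window_ms closed PN detection window.
#' @param fallback_ms automatic trigger time when nothing fired.
#' @param fallback_enabled issue the fallback trigger (TRUE matches the
#'   implemented system; FALSE leaves undetected trials without an event).
#' @param fn_mode offline false-negative rule: "default" (no PN-window
#'   packet satisfies the trigger rule) or "strict" (no PN-window packet is
#'   entirely motor intent).
#' @export
harnessSpec <- function(tick_ms = 50, packet_len_samples = 25,
                        trigger_fraction = 0.8, detection_start_ms = 1500,
                        rest_window_ms = c(1500, 2500),
                        pn_window_ms = c(2500, 3500),
                        fallback_ms = 3500, fallback_enabled = TRUE,
                        fn_mode = c("default", "strict")) {
  fn_mode <- match.arg(fn_mode)
  if (trigger_fraction <= 0 || trigger_fraction > 1)
    stop("trigger_fraction must be in (0, 1]")
  stopifnot(tick_ms > 0, packet_len_samples > 0,
            rest_window_ms[2] <= pn_window_ms[1],
            fallback_ms == pn_window_ms[2],
            detection_start_ms == rest_window_ms[1])
  list(tick_ms = tick_ms, packet_len_samples = packet_len_samples,
       trigger_fraction = trigger_fraction,
       detection_start_ms = detection_start_ms,
       rest_window_ms = rest_window_ms, pn_window_ms = pn_window_ms,
       fallback_ms = fallback_ms, fallback_enabled = fallback_enabled,
       fn_mode = fn_mode)
}

#' Packet trigger rule
#'
#' Fires iff at least `ceil(fraction * length)` samples of the packet are
#' labeled motor intent (80% of 25 samples = 20 by default).
#'
#' @param positive_count number of motor-intent samples in the packet.
#' @param length packet length.
#' @param fraction trigger fraction in (0, 1].
#' @export
triggerRule <- function(positive_count, length, fraction = 0.8) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (any(length <= 0)) stop("packet length must be > 0")
  positive_count >= ceiling(fraction * length)
}

#' Classify a decision timestamp into the trial windows
#'
#' @param timeMs decision timestamp, ms after preparation start.
#' @param spec a [harnessSpec()].
#' @return "pre_window", "rest" (a trigger here is a false positive), "pn"
#'   (a trigger here is a true positive), or "post_window".
#' @export
classifyEventWindow <- function(timeMs, spec = harnessSpec()) {
  if (any(timeMs < 0)) stop("negative time")
  vapply(timeMs, function(t) {
    if (t < spec$rest_window_ms[1]) "pre_window"
    else if (t < spec$rest_window_ms[2]) "rest"
    else if (t <= spec$pn_window_ms[2]) "pn"
    else "post_window"
  }, character(1))
}

#' Offline false-negative rule
#'
#' A trial is a false negative when no packet whose decision timestamp lies
#' in the PN window indicates motor intent: under the default rule, none
#' satisfies the trigger rule; under the strict rule (the literal reading
#' of "a total of 50 samples indicating motor intent"), none is entirely
#' motor intent. Computed from the stored per-tick log, independent of the
#' live event.
#'
#' @param log per-tick decision log from [runTrial()] (columns `time_ms`,
#'   `positive_count`, `length`).
#' @param spec a [harnessSpec()].
#' @param mode "default" or "strict" (defaults to the harness
#'   specification's `fn_mode`).
#' @export
offlineFalseNegative <- function(log, spec = harnessSpec(), mode = spec$fn_mode) {
  inPn <- log$time_ms >= spec$pn_window_ms[1] & log$time_ms <= spec$pn_window_ms[2]
  if (!any(inPn)) stop("decision log does not cover the PN window")
  pn <- log[inPn, , drop = FALSE]
  hit <- if (mode == "strict") pn$positive_count == pn$length
         else triggerRule(pn$positive_count, pn$length, spec$trigger_fraction)
  !any(hit)
}

# one tick decision for any detector kind; packet is channels x len with
# rownames, elapsed is the decision timestamp in ms
tickDecision <- function(model, packet, elapsedMs, spec) {
  len <- ncol(packet)
  if (is(model, "AveragePNDetector")) {
    fired <- averagePnDecision(elapsedMs, model@avgPnMs)
    list(positive_count = if (fired) len else 0L, length = len, fired = fired)
  } else if (is(model, "ThresholdDetector")) {
    x <- packet[model@channels[1], ]
    if (model@negatePolarity) x <- -x
    fired <- thresholdDecision(x, model@threshold)
    list(positive_count = if (fired) len else 0L, length = len, fired = fired)
  } else {
    dec <- classifyPacket(model, packet)
    list(positive_count = dec$positive_count, length = dec$length,
         fired = triggerRule(dec$positive_count, dec$length,
                             spec$trigger_fraction))
  }
}

# add a virtual-Cz row when the model asks for it, then restrict the stream
# to the model's channel order
streamForModel <- function(stream, model) {
  chans <- model@channels
  if (!length(chans)) return(stream)
  if ("VCz" %in% chans && !"VCz" %in% rownames(stream)) {
    vcz <- colMeans(stream[c("C1", "C3", "Cz"), , drop = FALSE])
    stream <- rbind(stream, VCz = vcz)
  }
  missing <- setdiff(chans, rownames(stream))
  if (length(missing))
    stop("stream lacks model channel(s): ", paste(missing, collapse = ", "))
  stream[chans, , drop = FALSE]
}

#' Run one trial through the tick harness
#'
#' Ticks advance every `tick_ms` from `detection_start_ms`; at each tick
#' the latest `packet_len_samples` samples are classified. The trial's
#' detection event is the first tick that fires (categorized by its
#' window), or the fallback at `fallback_ms`. The per-tick decision log
#' always covers the full detection span so the offline false-negative
#' rule is independent of the live event.
#'
#' @param model a [DetectorModel-class].
#' @param stream preprocessed (causal-path) channels x samples matrix with
#'   row names; sample 0 is the preparation-start trigger.
#' @param rate sampling rate (Hz).
#' @param spec a [harnessSpec()].
#' @return list with `time_ms`, `category` (true_positive / false_positive
#'   / fallback / none), `fn` (offline false-negative flag), and `log`.
#' @export
runTrial <- function(model, stream, rate, spec = harnessSpec()) {
  needed <- msToSamples(spec$fallback_ms, rate)
  if (ncol(stream) < needed)
    stop(sprintf("stream too short: %d samples, need %d to reach the fallback window",
                 ncol(stream), needed))
  stream <- streamForModel(stream, model)
  ticks <- seq(spec$detection_start_ms, spec$fallback_ms, by = spec$tick_ms)
  len <- spec$packet_len_samples
  log <- data.frame(time_ms = ticks, positive_count = NA_integer_,
                    length = len, fired = NA)
  for (i in seq_along(ticks)) {
    endSample <- msToSamples(ticks[i], rate)          # exclusive
    from <- endSample - len
    if (from < 0) stop("packet extends before the stream start")
    packet <- stream[, (from + 1L):endSample, drop = FALSE]
    dec <- tickDecision(model, packet, ticks[i], spec)
    log$positive_count[i] <- dec$positive_count
    log$fired[i] <- dec$fired
  }
  firstFire <- which(log$fired)[1]
  if (!is.na(firstFire)) {
    timeMs <- ticks[firstFire]
    win <- classifyEventWindow(timeMs, spec)
    category <- if (win == "pn") "true_positive" else "false_positive"
  } else if (spec$fallback_enabled) {
    timeMs <- spec$fallback_ms
    category <- "fallback"
  } else {
    timeMs <- NA_real_
    category <- "none"
  }
  list(time_ms = timeMs, category = category,
       fn = offlineFalseNegative(log, spec), log = log)
}

#' Run a session through the tick harness
#'
#' Preprocesses each block with the causal (real-time) filter path,
#' slices trials at their preparation-start triggers, runs each through
#' [runTrial()], and aggregates Table-style session statistics: accuracy
#' (percentage of trials triggered in the PN window), false positives
#' (triggered during rest), fallback count, and the offline false-negative
#' rate.
#'
#' @param model a [DetectorModel-class].
#' @param bundle a [SessionBundle-class].
#' @param spec a [harnessSpec()].
#' @param filter causal [filterSpec()] for the real-time path.
#' @param spatial "laplacian" or "none".
#' @param keepLogs retain per-tick logs in the report's `logs` attribute.
#' @return a [SessionReport-class].
#' @export
runSession <- function(model, bundle, spec = harnessSpec(),
                       filter = filterSpec(mode = "causal"),
                       spatial = "laplacian", keepLogs = FALSE) {
  rows <- NULL
  logs <- list()
  for (b in seq_along(bundle@recordings)) {
    pre <- preprocess(bundle@recordings[[b]], filter, spatial = spatial)
    trials <- extractTrials(pre)
    for (k in seq_len(nrow(trials))) {
      streamCols <- (trials$prep[k] + 1L):trials$end[k]
      stream <- pre@data[, streamCols, drop = FALSE]
      out <- runTrial(model, stream, pre@rate, spec)
      rows <- rbind(rows, data.frame(block = b, trial = k,
                                     time_ms = out$time_ms,
                                     category = out$category, fn = out$fn))
      if (keepLogs) logs[[length(logs) + 1L]] <- out$log
    }
  }
  n <- nrow(rows)
  counts <- c(tp = sum(rows$category == "true_positive"),
              fp = sum(rows$category == "false_positive"),
              fallback = sum(rows$category == "fallback"),
              none = sum(rows$category == "none"))
  rep <- new("SessionReport", trials = rows,
             fpRate = 100 * counts[["fp"]] / n,
             fnRate = 100 * sum(rows$fn) / n,
             accuracy = 100 * counts[["tp"]] / n,
             counts = counts)
  if (keepLogs) attr(rep, "logs") <- logs
  rep
}
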