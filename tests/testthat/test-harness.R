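# A stream of preprocessed zeros on the model's channels, long enough to
# cover the fallback window.
zeroStream <- function(nSamples = 2500, channels = sensorimotorChannels()) {
  matrix(0, length(channels), nSamples, dimnames = list(channels, NULL))
}

test_that("trigger rule: 80% of the packet, ceiling semantics, boundaries", {
  expect_true(triggerRule(20, 25))
  expect_false(triggerRule(19, 25))
  expect_true(triggerRule(40, 50))
  expect_false(triggerRule(39, 50))
  expect_true(triggerRule(25, 25, fraction = 1.0))
  expect_false(triggerRule(24, 25, fraction = 1.0))
  expect_error(triggerRule(5, 25, fraction = 0), "fraction")
  expect_error(triggerRule(5, 25, fraction = 1.5), "fraction")
  expect_error(triggerRule(5, 0), "length")
})

test_that("decision timestamps partition into the protocol windows", {
  spec <- harnessSpec()
  expect_equal(classifyEventWindow(1000, spec), "pre_window")
  expect_equal(classifyEventWindow(2000, spec), "rest")
  expect_equal(classifyEventWindow(2499, spec), "rest")
  expect_equal(classifyEventWindow(2500, spec), "pn")    # half-open rest
  expect_equal(classifyEventWindow(3500, spec), "pn")    # closed PN end
  expect_equal(classifyEventWindow(3501, spec), "post_window")
  expect_error(classifyEventWindow(-1, spec), "negative")
})

test_that("always-rest stub falls back at exactly 3500 ms and is an offline FN", {
  neverFire <- averagePnDetector(1e9)
  out <- runTrial(neverFire, zeroStream(), 500)
  expect_equal(out$time_ms, 3500)
  expect_equal(out$category, "fallback")
  expect_true(out$fn)
  # with the fallback disabled the trial carries no stimulation event
  spec <- harnessSpec(fallback_enabled = FALSE)
  out2 <- runTrial(neverFire, zeroStream(), 500, spec)
  expect_equal(out2$category, "none")
  expect_true(is.na(out2$time_ms))
  expect_true(out2$fn)
})

test_that("always-intent stub triggers at detection start, a false positive", {
  always <- averagePnDetector(0)
  out <- runTrial(always, zeroStream(), 500)
  expect_equal(out$time_ms, 1500)
  expect_equal(out$category, "false_positive")
})

test_that("intent from 2600 ms triggers on the tick grid as a true positive", {
  out <- runTrial(averagePnDetector(2600), zeroStream(), 500)
  expect_equal(out$time_ms, 2600)
  expect_equal(out$category, "true_positive")
  # oracle: brute-force scan of the tick grid for the first eligible tick
  ticks <- seq(1500, 3500, by = 50)
  expect_equal(out$time_ms, min(ticks[ticks >= 2600]))
  # a stub not aligned to the grid is quantized up to the next tick
  out2 <- runTrial(averagePnDetector(2910), zeroStream(), 500)
  expect_equal(out2$time_ms, 2950)
  expect_true(out2$time_ms >= 2910 && out2$time_ms <= 2910 + 50)
})

test_that("average-PN firing time is identical across a session (open loop)", {
  b <- simulateSession(quietPlan(n_blocks = 2, seed = 31))
  rep <- runSession(averagePnDetector(2940), b)
  expect_equal(unique(rep@trials$time_ms), 2950)
  expect_equal(rep@accuracy, 100)
})

test_that("harness bookkeeping is invariant to packet length for ms-defined stubs", {
  for (stubTime in c(0, 2600, 1e9)) {
    stub <- averagePnDetector(stubTime)
    o25 <- runTrial(stub, zeroStream(), 500, harnessSpec(packet_len_samples = 25))
    o50 <- runTrial(stub, zeroStream(), 500, harnessSpec(packet_len_samples = 50))
    expect_equal(o25$time_ms, o50$time_ms)
    expect_equal(o25$category, o50$category)
    expect_equal(o25$fn, o50$fn)
  }
})

test_that("offline FN rule: default vs strict packet reading", {
  spec <- harnessSpec()
  mkLog <- function(countsAt3000) {
    ticks <- seq(1500, 3500, by = 50)
    data.frame(time_ms = ticks,
               positive_count = ifelse(ticks == 3000, countsAt3000, 0L),
               length = 25L)
  }
  expect_false(offlineFalseNegative(mkLog(25), spec))            # both modes
  expect_false(offlineFalseNegative(mkLog(25), spec, "strict"))
  expect_false(offlineFalseNegative(mkLog(21), spec))            # >= 20 of 25
  expect_true(offlineFalseNegative(mkLog(21), spec, "strict"))   # not all 25
  expect_true(offlineFalseNegative(mkLog(19), spec))
  short <- data.frame(time_ms = seq(1500, 2400, 50), positive_count = 0L,
                      length = 25L)
  expect_error(offlineFalseNegative(short, spec), "PN window")
})

test_that("stream shorter than the fallback window is rejected", {
  expect_error(runTrial(averagePnDetector(0), zeroStream(1000), 500),
               "too short")
})

test_that("live categorization equals a brute-force recount of the tick logs", {
  b <- simulateSession(quietPlan(n_blocks = 2, seed = 41))
  cal <- calibrateSession(b)
  model <- thresholdDetector(cal$calibration@thresholdValue,
                             cal$calibration@thresholdK)
  spec <- harnessSpec()
  rep <- runSession(model, b, spec, keepLogs = TRUE)
  logs <- attr(rep, "logs")
  expect_length(logs, nTrials(b))
  for (i in seq_along(logs)) {
    log <- logs[[i]]
    fired <- which(log$fired)
    if (length(fired)) {
      tm <- log$time_ms[fired[1]]
      cat. <- if (classifyEventWindow(tm, spec) == "pn") "true_positive"
              else "false_positive"
    } else {
      tm <- spec$fallback_ms; cat. <- "fallback"
    }
    expect_equal(rep@trials$time_ms[i], tm)
    expect_equal(rep@trials$category[i], cat.)
    expect_equal(rep@trials$fn[i], offlineFalseNegative(log, spec))
  }
  expect_equal(sum(rep@counts), nTrials(b))
  expect_equal(rep@fpRate, 100 * rep@counts[["fp"]] / nTrials(b))
  expect_equal(rep@accuracy, 100 * rep@counts[["tp"]] / nTrials(b))
})

test_that("session report rates follow stub firing schedules", {
  b <- simulateSession(quietPlan(n_blocks = 2, seed = 51))
  # perfect stub: fires inside the PN window every trial
  perfect <- runSession(averagePnDetector(3000), b)
  expect_equal(perfect@accuracy, 100)
  expect_equal(perfect@fpRate, 0)
  expect_equal(perfect@fnRate, 0)
  # always-rest stub: all fallback, all FN
  never <- runSession(averagePnDetector(1e9), b)
  expect_equal(never@counts[["fallback"]], nTrials(b))
  expect_equal(never@fnRate, 100)
  # early stub: fires during rest -> 100% false positives
  early <- runSession(averagePnDetector(2000), b)
  expect_equal(early@fpRate, 100)
  expect_equal(early@accuracy, 0)
})
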