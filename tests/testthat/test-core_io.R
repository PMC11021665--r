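test_that("bundle write/read is the identity on data, rate, labels, triggers", {
  b <- simulateSession(noiselessPlan())
  path <- withr::local_tempfile(fileext = ".rds")
  writeBundle(b, path)
  b2 <- readBundle(path)
  expect_identical(eegData(b2@recordings[[1]]), eegData(b@recordings[[1]]))
  expect_identical(samplingRate(b2@recordings[[1]]), samplingRate(b@recordings[[1]]))
  expect_identical(channelNames(b2@recordings[[1]]), channelNames(b@recordings[[1]]))
  expect_identical(events(b2@recordings[[1]]), events(b@recordings[[1]]))
  expect_identical(groundTruth(b2), groundTruth(b))

  r <- b@recordings[[1]]
  path2 <- withr::local_tempfile(fileext = ".rds")
  writeBundle(r, path2)
  expect_identical(eegData(readRecording(path2, "bundle")), eegData(r))
})

test_that("EDF fixture round-trips shape, amplitudes, and trigger samples", {
  rate <- 500
  set.seed(4)
  data <- matrix(rnorm(2 * 10 * rate, sd = 20), nrow = 2,
                 dimnames = list(c("Cz", "C3"), NULL))
  ev <- data.frame(code = c(8L, 6L, 7L), sample = c(0L, 1500L, 4999L))
  path <- withr::local_tempfile(fileext = ".edf")
  writeEdfFixture(path, data, rate, ev)
  r <- readRecording(path, "edf")
  expect_equal(dim(eegData(r)), c(2, 5000))
  expect_identical(channelNames(r), c("Cz", "C3"))
  expect_equal(samplingRate(r), rate)
  # 0.1 uV quantization of the int16 writer
  expect_lt(max(abs(eegData(r) - data)), 0.05 + 1e-9)
  expect_identical(events(r)$code, ev$code)
  expect_identical(events(r)$sample, ev$sample)

  noEv <- withr::local_tempfile(fileext = ".edf")
  writeEdfFixture(noEv, data, rate, events = NULL)
  expect_error(readRecording(noEv, "edf"), "no events")
})

test_that("BrainVision markers map to 0-based samples with exact codes", {
  rate <- 500
  set.seed(5)
  data <- matrix(rnorm(3 * 2 * rate), nrow = 3,
                 dimnames = list(c("Cz", "C1", "C3"), NULL))
  ev <- data.frame(code = c(8L, 6L, 7L), sample = c(10L, 250L, 900L))
  dir <- withr::local_tempdir()
  vhdr <- writeBrainVisionFixture(dir, "fix", data, rate, ev)
  r <- readRecording(vhdr, "brainvision")
  expect_equal(dim(eegData(r)), c(3, 1000))
  expect_equal(eegData(r), data, ignore_attr = TRUE, tolerance = 1e-6)
  # oracle: independent text parse of the marker file
  mrk <- readLines(file.path(dir, "fix.vmrk"))
  stim <- grep("^Mk[0-9]+=Stimulus", mrk, value = TRUE)
  parts <- strsplit(sub("^Mk[0-9]+=", "", stim), ",")
  oracle <- data.frame(
    code = as.integer(gsub("[^0-9]", "", vapply(parts, `[`, "", 2))),
    sample = as.integer(vapply(parts, `[`, "", 3)) - 1L)
  expect_identical(events(r)$code, oracle$code)
  expect_identical(events(r)$sample, oracle$sample)
})

test_that("extractTrials slices the protocol stream and flags malformed trials", {
  m <- validateMontage(c("Cz", "C1"))
  mkRec <- function(codes, samples, n = 6000) {
    eegRecording(matrix(0, 2, n, dimnames = list(c("Cz", "C1"), NULL)), 500,
                 m, data.frame(code = codes, sample = samples))
  }
  # five trials closed by a code-7 block end
  r <- mkRec(c(rep(c(8, 6), 5), 7),
             c(t(cbind(0:4 * 1000, 0:4 * 1000 + 300)), 5500))
  tr <- extractTrials(r)
  expect_equal(nrow(tr), 5)
  expect_equal(tr$start, 0:4 * 1000)
  expect_equal(tr$prep, 0:4 * 1000 + 300)
  expect_true(all(tr$end[-5] == tr$start[-1]))
  expect_equal(tr$end[5], 5500)
  expect_true(all(tr$start < tr$prep & tr$prep < tr$end))

  expect_equal(nrow(extractTrials(mkRec(integer(0), integer(0)))), 0)
  expect_error(extractTrials(mkRec(c(8, 8, 6), c(0, 100, 200))),
               "malformed trial 1")
  # non-protocol codes are preserved in events but ignored by slicing
  r2 <- mkRec(c(8, 99, 6, 7), c(0, 50, 300, 900))
  expect_equal(nrow(extractTrials(r2)), 1)
  expect_true(99 %in% events(r2)$code)
})

test_that("extractTrials count equals code-8 count on well-formed streams", {
  m <- validateMontage(c("Cz", "C1"))
  set.seed(9)
  for (rep in 1:10) {
    nT <- sample(1:6, 1)
    starts <- cumsum(sample(500:1500, nT))
    codes <- c(rbind(8, 6))
    samples <- c(rbind(starts, starts + sample(100:400, nT)))
    r <- eegRecording(matrix(0, 2, max(samples) + 1000,
                             dimnames = list(c("Cz", "C1"), NULL)), 500, m,
                      data.frame(code = codes, sample = samples))
    expect_equal(nrow(extractTrials(r)), nT)
  }
})

test_that("validateMontage covers the sensorimotor set, rejects duplicates, is symmetric", {
  m <- standardMontage()
  expect_length(channelNames(m), 64)
  expect_true(all(sensorimotorChannels() %in% channelNames(m)))
  expect_error(validateMontage(c("Cz", "Cz")), "duplicate")
  for (ch in channelNames(m)) {
    for (nb in m@neighbors[[ch]])
      expect_true(ch %in% m@neighbors[[nb]])
  }
  # unknown labels are kept but flagged
  m2 <- validateMontage(c("Cz", "EMG1"))
  expect_identical(attr(m2, "unrecognized"), "EMG1")
})

test_that("event CSV export carries code, sample, and seconds", {
  r <- simulateSession(noiselessPlan())@recordings[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  exportEvents(r, path)
  ev <- read.csv(path)
  expect_identical(names(ev), c("code", "sample", "time_s"))
  expect_equal(ev$time_s, ev$sample / samplingRate(r))
  expect_equal(nrow(ev), nrow(events(r)))
})
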