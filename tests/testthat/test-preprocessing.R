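# helper: wrap a plain matrix as a recording on montage labels
recOf <- function(data, labels, rate = 500) {
  rownames(data) <- labels
  eegRecording(data, rate, validateMontage(labels))
}

test_that("band-pass rejects DC, passes 1 Hz, rejects 50 Hz", {
  rate <- 500
  n <- 20 * rate
  t <- (seq_len(n) - 1) / rate
  lab <- c("Cz", "C1")
  spec <- filterSpec()

  dc <- recOf(matrix(10, 2, n), lab)
  out <- eegData(bandpass(dc, spec))
  mid <- (5 * rate):(15 * rate)
  expect_lt(max(abs(out[, mid])), 0.1)          # < 1% of the 10 uV input

  s1 <- recOf(matrix(rep(sin(2 * pi * 1 * t), each = 2), 2, n, byrow = FALSE), lab)
  o1 <- eegData(bandpass(s1, spec))[1, mid]
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(o1) / rms(sin(2 * pi * 1 * t[mid])) - 1), 0.1)

  s50 <- recOf(matrix(rep(sin(2 * pi * 50 * t), each = 2), 2, n), lab)
  o50 <- eegData(bandpass(s50, spec))[1, mid]
  expect_lt(rms(o50) / rms(sin(2 * pi * 50 * t[mid])), 0.05)

  expect_error(bandpass(dc, filterSpec(high_hz = 300)), "Nyquist")
})

test_that("zero-phase filtering has no group delay; causal mode does", {
  rate <- 500
  n <- 20 * rate
  t <- (seq_len(n) - 1) / rate
  x <- sin(2 * pi * 2 * t)
  r <- recOf(matrix(x, 1, n), "Cz")
  y <- eegData(bandpass(r, filterSpec(mode = "offline_zero_phase")))[1, ]
  mid <- (5 * rate):(15 * rate)
  lags <- -25:25
  cc <- vapply(lags, function(L) cor(x[mid], y[mid + L]), numeric(1))
  expect_equal(lags[which.max(cc)], 0)
  yc <- eegData(bandpass(r, filterSpec(mode = "causal")))[1, ]
  ccc <- vapply(lags, function(L) cor(x[mid], yc[mid + L]), numeric(1))
  expect_gt(lags[which.max(ccc)], 0)            # forward-only filter lags
})

test_that("sensorimotor selection restricts to the canonical 20-channel order", {
  b <- simulateSession(noiselessPlan())
  r <- b@recordings[[1]]
  out <- selectSensorimotor(r)
  expect_identical(channelNames(out), sensorimotorChannels())
  expect_equal(nrow(eegData(out)), 20)
  # order is canonical regardless of input order
  shuffled <- validateMontage(rev(channelNames(r)))
  r2 <- eegRecording(eegData(r)[rev(channelNames(r)), ], samplingRate(r),
                     shuffled, events(r))
  expect_identical(channelNames(selectSensorimotor(r2)), sensorimotorChannels())

  sub <- setdiff(channelNames(r), "CPz")
  r3 <- eegRecording(eegData(r)[sub, ], samplingRate(r),
                     validateMontage(sub), events(r))
  expect_error(selectSensorimotor(r3), "CPz")
})

test_that("selection commutes with band-pass filtering", {
  b <- simulateSession(quietPlan(n_blocks = 1, seed = 3))
  r <- b@recordings[[1]]
  a <- eegData(selectSensorimotor(bandpass(r)))
  bb <- eegData(bandpass(selectSensorimotor(r)))
  expect_equal(a, bb, tolerance = 1e-9)
})

test_that("Laplacian: uniform-field null, hand-computed chain, linearity", {
  lab <- c("C3", "C1", "Cz")
  uni <- recOf(matrix(5, 3, 100), lab)
  expect_true(all(abs(eegData(laplacian(uni))) < 1e-12))

  # toy chain A-B-C with values (1, 5, 1): out(B) = 5 - (1+1)/2 = 4
  chain <- new("Montage", labels = c("A", "B", "C"),
               positions = matrix(c(0, 1, 2, 0, 0, 0), 3, 2,
                                  dimnames = list(c("A", "B", "C"), c("x", "y"))),
               neighbors = list(A = "B", B = c("A", "C"), C = "B"))
  r <- eegRecording(matrix(c(1, 5, 1), 3, 10,
                           dimnames = list(c("A", "B", "C"), NULL)),
                    500, chain)
  out <- eegData(laplacian(r))
  expect_equal(unname(out["B", 1]), 4)
  expect_equal(unname(out["A", 1]), 1 - 5)

  set.seed(6)
  x <- recOf(matrix(rnorm(300), 3, 100), lab)
  y <- recOf(matrix(rnorm(300), 3, 100), lab)
  xy <- recOf(eegData(x) + eegData(y), lab)
  expect_equal(eegData(laplacian(xy)),
               eegData(laplacian(x)) + eegData(laplacian(y)), tolerance = 1e-12)

  lonely <- new("Montage", labels = c("A", "B"),
                positions = matrix(0, 2, 2, dimnames = list(c("A", "B"), c("x", "y"))),
                neighbors = list(A = "B", B = "A"))
  r2 <- eegRecording(matrix(0, 2, 10, dimnames = list(c("A", "B"), NULL)), 500, lonely)
  noNb <- new("Montage", labels = c("A", "B"),
              positions = matrix(0, 2, 2, dimnames = list(c("A", "B"), c("x", "y"))),
              neighbors = list(A = character(0), B = character(0)))
  expect_error(laplacian(r2, noNb), "no neighbors")
})

test_that("virtual Cz is the mean of C1, C3, Cz", {
  lab <- c("C1", "C3", "Cz")
  r <- recOf(matrix(c(1, 2, 3), 3, 50), lab)
  expect_equal(unname(virtualCz(r)), rep(2, 50))
  set.seed(7)
  r2 <- recOf(matrix(rnorm(150), 3, 50), lab)
  expect_equal(virtualCz(r2), colMeans(eegData(r2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  r3 <- recOf(matrix(0, 2, 50), c("C1", "Cz"))
  expect_error(virtualCz(r3), "C3")
})

test_that("epoching yields the exact sample counts and trial counts", {
  b <- simulateSession(quietPlan(n_blocks = 2, seed = 12))
  r <- b@recordings[[1]]
  e1 <- epochRecording(r, "cue", c(-3000, 1000))
  expect_equal(dim(eegData(e1))[3], 2000)
  e2 <- epochRecording(r, "prep_start", c(1000, 4000))
  expect_equal(dim(eegData(e2))[3], 1500)
  expect_equal(nTrials(e2), 5)
  expect_error(epochRecording(r, "prep_start", c(-4000, 4000)), "trial 1")
})
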