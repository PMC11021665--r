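test_that("trialPnTime finds the window minimum with earliest-tie breaking", {
  rate <- 500
  n <- 2000                                  # epoch [1000, 5000) ms
  x <- rep(0, n)
  x[msToSamples(3120 - 1000, rate) + 1] <- -5   # dip at 3120 ms
  expect_equal(trialPnTime(x, cueMs = 3000, rate = rate, startMs = 1000), 3120)

  x2 <- rep(1, n)
  x2[msToSamples(3400 - 1000, rate) + 1] <- -2  # single dip at cue + 400
  expect_equal(trialPnTime(x2, 3000, rate, 1000), 3400)

  x3 <- rep(0, n)                               # all ties -> earliest sample
  expect_equal(trialPnTime(x3, 3000, rate, 1000), 2500)

  expect_error(trialPnTime(rep(0, 100), 3000, rate, 1000), "not covered")
})

test_that("PN extraction recovers simulator ground truth", {
  # noiseless, unfiltered epochs: exact to one sample for every trial
  b <- simulateSession(noiselessPlan(n_blocks = 2, jitter = 150))
  gt <- groundTruth(b)
  ep <- do.call(mrcpbci:::bindEpochs,
                lapply(b@recordings, epochRecording,
                       align = "cue", windowMs = c(-3000, 1000)))
  vcz <- virtualCz(ep)
  pn <- vapply(seq_len(nrow(vcz)), function(i)
    trialPnTime(vcz[i, ], cueMs = 3000, rate = 500, startMs = 0), numeric(1))
  expect_true(all(abs(pn - gt$pn_ms) <= 2))
  # default SNR through the full preprocessing chain: small mean absolute
  # error (the acceptance suite runs the 100-trial version of this check)
  bn <- simulateSession(quietPlan(n_blocks = 4, seed = 19))
  outn <- calibrateSession(bn)
  expect_lt(mean(abs(outn$calibration@pnTimesMs - groundTruth(bn)$pn_ms)), 60)
})

test_that("averagePn is the arithmetic mean, permutation invariant", {
  expect_equal(averagePn(c(2900, 3000, 3100)), 3000)
  expect_equal(averagePn(3050), 3050)
  expect_error(averagePn(numeric(0)), "no PN")
  set.seed(3)
  v <- runif(20, 2500, 3500)
  expect_equal(averagePn(v), averagePn(sample(v)))
})

test_that("ERP averaging: identity, cancellation, 1/sqrt(N) noise shrinkage", {
  mk <- function(arr) new("EpochSet", data = arr, rate = 500,
                          channels = c("Cz", "C1"), windowMs = c(0, 1000),
                          align = "prep_start",
                          labels = matrix(integer(), 0, 0), refsMs = numeric(0))
  one <- array(rnorm(2 * 500), c(1, 2, 500))
  same <- array(rep(one, each = 3), c(3, 2, 500))
  for (k in 1:3) same[k, , ] <- one[1, , ]
  expect_equal(buildErp(mk(same)), one[1, , ], ignore_attr = TRUE)

  pm <- array(0, c(2, 2, 500))
  pm[1, , ] <- one[1, , ]; pm[2, , ] <- -one[1, , ]
  expect_true(all(abs(buildErp(mk(pm))) < 1e-12))

  rms <- function(x) sqrt(mean(x^2))
  set.seed(8)
  ratio <- vapply(c(4, 16, 64), function(N) {
    arr <- array(rnorm(N * 2 * 500), c(N, 2, 500))
    rms(buildErp(mk(arr))) / rms(arr[1, , ])
  }, numeric(1))
  expect_equal(ratio, 1 / sqrt(c(4, 16, 64)), tolerance = 0.25)

  expect_error(buildErp(mk(array(0, c(0, 2, 500)))), "at least one")
})

test_that("threshold is rest mean + k SD on the polarity-adjusted series", {
  rate <- 500
  set.seed(10)
  rest <- rnorm(500)                       # first second of the epoch
  erp <- c(rest, rnorm(1500, -3))
  thr <- computeThreshold(-erp, rate, k = 2, negate = FALSE)
  expect_equal(thr, mean(-rest) + 2 * sd(-rest), tolerance = 1e-9)
  # negation handled internally: same value from the raw series
  expect_equal(computeThreshold(erp, rate, k = 2), thr, tolerance = 1e-9)

  const <- rep(1.5, 2000)
  expect_equal(computeThreshold(const, rate, k = 3), -1.5)   # negated constant

  expect_error(computeThreshold(erp, rate, k = 5), "k must be")
  expect_silent(computeThreshold(erp, rate, k = 5, allowAnyK = TRUE))
  expect_error(computeThreshold(erp[1:100], rate, k = 1), "rest window")
})

test_that("sample labeling creates disjoint 1-s intent and rest windows", {
  arr <- array(0, c(3, 3, 1500))           # epochs [1000, 4000) at 500 Hz
  ep <- new("EpochSet", data = arr, rate = 500, channels = c("Cz", "C1", "C3"),
            windowMs = c(1000, 4000), align = "prep_start",
            labels = matrix(integer(), 0, 0), refsMs = numeric(0))
  lab <- labelSamples(ep, labelingScheme("time_based"), refsMs = 3000)
  L <- epochLabels(lab)
  # intent [2500, 3500) -> samples 751..1250; rest [1500, 2500) -> 251..750
  expect_true(all(L[1, 751:1250] == 1))
  expect_true(all(L[1, 251:750] == 0))
  expect_true(all(is.na(L[1, c(1:250, 1251:1500)])))
  expect_equal(sum(L[1, ] == 1, na.rm = TRUE), 500)
  expect_equal(sum(L[1, ] == 0, na.rm = TRUE), 500)
  # per-trial PN-based references shift the windows trial by trial
  lab2 <- labelSamples(ep, labelingScheme("pn_based"), refsMs = c(3200, 3000, 2900))
  L2 <- epochLabels(lab2)
  expect_true(all(L2[1, 851:1350] == 1))   # intent [2700, 3700)
  expect_true(all(L2[1, 351:850] == 0))    # rest [1700, 2700)
  # disjointness for every trial
  for (k in 1:3) expect_equal(sum(!is.na(L2[k, ])), 1000)
  # a reference too near the epoch edge errors with the trial index
  expect_error(labelSamples(ep, labelingScheme("pn_based"),
                            refsMs = c(3000, 3000, 3600)), "trial 3")
})

test_that("calibrateSession assembles consistent results", {
  b <- simulateSession(quietPlan(n_blocks = 2, seed = 23))
  out <- calibrateSession(b, nTrials = 8)
  cal <- out$calibration
  expect_length(pnTimes(cal), 8)
  expect_equal(cal@avgPnMs, mean(pnTimes(cal)))
  expect_true(all(pnTimes(cal) >= 2500 & pnTimes(cal) <= 3500))
  expect_equal(nTrials(out$dataset), 8)
  expect_equal(dim(eegData(out$dataset))[3], 1500)
  expect_equal(rownames(cal@erp), sensorimotorChannels())
})
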