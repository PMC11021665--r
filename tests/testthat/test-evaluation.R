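test_that("sample accuracy counts labeled samples only", {
  lab <- c(rep(1L, 25), rep(0L, 25))
  pred <- lab; pred[1:5] <- 0L
  expect_equal(sampleAccuracy(pred, lab)$accuracy, 45 / 50)
  expect_equal(sampleAccuracy(lab, lab)$accuracy, 1.0)
  expect_equal(sampleAccuracy(1L - lab, lab)$accuracy, 0.0)
  # unlabeled samples are excluded
  lab2 <- c(lab, rep(NA, 30))
  pred2 <- c(pred, rep(1L, 30))
  expect_equal(sampleAccuracy(pred2, lab2)$n, 50)
  expect_equal(sampleAccuracy(pred2, lab2)$accuracy, 45 / 50)
  expect_error(sampleAccuracy(1:3, 1:4), "same length")
  # permutation invariance under a joint shuffle
  set.seed(1)
  i <- sample(length(lab))
  expect_equal(sampleAccuracy(pred[i], lab[i])$accuracy, 45 / 50)
  # random balanced predictions sit at chance (binomial oracle)
  set.seed(2)
  n <- 1e4
  r <- sampleAccuracy(sample(0:1, n, TRUE), sample(0:1, n, TRUE))
  expect_lt(abs(r$accuracy - 0.5), 0.02)
})

test_that("detection error: sign convention, identities, degenerate cases", {
  e <- detectionError(2900, 3000)
  expect_equal(e$mean, -100)          # negative = fired before the PN
  expect_equal(e$rmse, 100)
  z <- detectionError(c(3000, 3100), c(3000, 3100))
  expect_equal(z$mean, 0); expect_equal(z$sd, 0); expect_equal(z$rmse, 0)
  expect_error(detectionError(numeric(0), numeric(0)), "no trials")
  expect_error(detectionError(1:3, 1:2), "same length")

  # RMSE^2 = mean^2 + var * (n-1)/n, RMSE >= |mean|
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    r <- detectionError(rnorm(n, 3000, 120), rnorm(n, 3000, 80))
    expect_equal(r$rmse^2, r$mean^2 + var(r$errors) * (n - 1) / n,
                 tolerance = 1e-9)
    expect_gte(r$rmse, abs(r$mean) - 1e-12)
  }
})

test_that("fivefold evaluation repeats a fixed chronological split over seeds", {
  set.seed(4)
  nCh <- 20; nS <- 100; n <- 10
  arr <- array(rnorm(n * nCh * nS, sd = 0.5), c(n, nCh, nS))
  lab <- matrix(NA_integer_, n, nS)
  lab[, 1:40] <- 0L; lab[, 51:90] <- 1L
  for (k in seq_len(n)) arr[k, , 51:90] <- arr[k, , 51:90] - 3
  ds <- new("EpochSet", data = arr, rate = 500,
            channels = sensorimotorChannels(), windowMs = c(0, 200),
            align = "prep_start", labels = lab, refsMs = rep(0, n))

  # deterministic trainer (ignores the seed): SD is exactly zero
  fixed <- trainMLP(mrcpbci:::subsetEpochs(ds, 1:5), tinyMlp(seed = 1))
  det <- fivefoldEval(ds, function(train, seed) fixed)
  expect_length(det$fold, 5)
  expect_equal(det$sd, 0)

  # seeded trainer matches a manually scripted loop exactly
  trainer <- function(train, seed) trainMLP(train, tinyMlp(seed = seed))
  ff <- fivefoldEval(ds, trainer, seeds = 1:5)
  manual <- vapply(1:5, function(s) {
    m <- trainer(mrcpbci:::subsetEpochs(ds, 1:5), s)
    heldOutAccuracy(m, mrcpbci:::subsetEpochs(ds, 6:10))
  }, numeric(1))
  expect_equal(ff$fold, manual, tolerance = 1e-12)
  expect_equal(ff$mean, mean(manual), tolerance = 1e-12)
  expect_error(fivefoldEval(mrcpbci:::subsetEpochs(ds, 1), trainer),
               "two trials")
})

test_that("two-sample t test matches the classic pooled form", {
  same <- twoSampleTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  far <- twoSampleTest(c(1, 2, 3), c(11, 12, 13))
  expect_lt(far$p, 0.001)
  expect_error(twoSampleTest(1, c(1, 2)), ">= 2")
  expect_error(twoSampleTest(c(1, 1), c(2, 2)), "degenerate")
  set.seed(5)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  ours <- twoSampleTest(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
})

test_that("ERD in dB follows the power ratio; laterality index is the stated ratio", {
  mk <- function(amp, seed = 6) {
    withr::with_seed(seed, {
      n <- 20; nS <- 1000; rate <- 500
      t <- (seq_len(nS) - 1) / rate
      arr <- array(0, c(n, 2, nS))
      for (k in seq_len(n))
        for (ch in 1:2)
          arr[k, ch, ] <- amp * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi)) +
            rnorm(nS, sd = 0.01)
      new("EpochSet", data = arr, rate = rate, channels = c("C3", "C4"),
          windowMs = c(0, 2000), align = "cue",
          labels = matrix(integer(), 0, 0), refsMs = numeric(0))
    })
  }
  rest <- mk(2, seed = 7)
  expect_equal(erd(rest, rest, "alpha"), 0)
  # amplitude halved during movement -> 20*log10(2) = 6.02 dB
  expect_equal(erd(mk(1, seed = 8), rest, "alpha"), 20 * log10(2),
               tolerance = 0.1)
  # power ratio of 10 -> 10 dB, via the numeric band interface
  expect_equal(erd(mk(2 / sqrt(10), seed = 9), rest, c(8, 12)), 10,
               tolerance = 0.15)

  expect_equal(lateralityIndex(6, 2), 0.5)
  expect_equal(lateralityIndex(4, 4), 0)
  expect_equal(lateralityIndex(3, 0), 1.0)
  expect_error(lateralityIndex(1, -1), "zero denominator")
})
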