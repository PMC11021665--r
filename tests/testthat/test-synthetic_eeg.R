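test_that("mrcpTemplate anchors: degenerate jitter, exact minimum at the PN", {
  tl <- trialTimeline()
  p0 <- mrcpParams(pn_jitter_sd_ms = 0)
  tmpl <- withr::with_seed(1, mrcpTemplate(p0, tl))
  expect_equal(tmpl$true_pn_ms, 3000)            # exactly the cue
  expect_equal(min(tmpl$waveform), p0$pn_amplitude)
  pnAbs <- tl$relax_ms + tmpl$true_pn_ms
  expect_equal(which.min(tmpl$waveform) - 1L, msToSamples(pnAbs, tl$rate))
  # zero before the ramp onset, monotone decreasing down to the PN
  rampStart <- msToSamples(pnAbs - mrcpParams()$ramp_start_ms, tl$rate)
  expect_true(all(tmpl$waveform[1:rampStart] == 0))
  ramp <- tmpl$waveform[(rampStart + 1):(msToSamples(pnAbs, tl$rate) + 1)]
  expect_true(all(diff(ramp) <= 1e-12))
})

test_that("PN jitter is truncated-normal with the expected spread", {
  draws <- withr::with_seed(2, vapply(1:1000, function(i)
    mrcpTemplate(mrcpParams(), trialTimeline())$true_pn_ms, numeric(1)))
  expect_true(all(draws >= 2550 & draws < 3450 + 1e-9))
  # oracle: truncated-normal moments - sd 150 truncated at 3 sd has
  # SD ~146, well inside the [135, 165] acceptance band
  expect_gt(sd(draws), 135)
  expect_lt(sd(draws), 165)
  expect_lt(abs(mean(draws) - 3000), 15)
})

test_that("noiseless trials recover the injected PN to the sample", {
  b <- simulateSession(sessionPlan(n_blocks = 1, seed = 33,
                                   noise = noiseParams(0, 0, 0, 0)))
  r <- b@recordings[[1]]
  gt <- groundTruth(b)
  trials <- extractTrials(r)
  cz <- eegData(r)["Cz", ]
  for (k in seq_len(nrow(trials))) {
    seg <- cz[(trials$prep[k] + 1):trials$end[k]]
    win <- seg[(msToSamples(2500, 500) + 1):(msToSamples(3500, 500))]
    est <- 2500 + (which.min(win) - 1) * 2
    expect_lt(abs(est - gt$pn_ms[k]), 2 + 1e-9)
  }
})

test_that("template energy is midline-central: far channels get < 10% of Cz", {
  plan <- sessionPlan(n_blocks = 1, seed = 7, noise = noiseParams(0, 0, 0, 0))
  tr <- withr::with_seed(plan$seed, simulateTrial(plan))
  eCz <- sum(tr$data["Cz", ]^2)
  eO2 <- sum(tr$data["O2", ]^2)
  expect_lt(eO2, 0.1 * eCz)
  # oracle: the Gaussian falloff evaluated at the montage distance
  m <- standardMontage()
  d <- mrcpbci:::montageDistances(m, "Cz")[["O2"]]
  gain <- exp(-d^2 / (2 * plan$topo$falloff_sd^2))
  expect_equal(eO2 / eCz, gain^2, tolerance = 1e-6)
})

test_that("simulation is a pure function of (plan, seed)", {
  plan <- quietPlan(n_blocks = 1, seed = 55)
  b1 <- simulateSession(plan)
  b2 <- simulateSession(plan)
  expect_identical(eegData(b1@recordings[[1]]), eegData(b2@recordings[[1]]))
  expect_identical(groundTruth(b1), groundTruth(b2))
  b3 <- simulateSession(sessionPlan(n_blocks = 1, seed = 56))
  expect_false(identical(eegData(b1@recordings[[1]]),
                         eegData(b3@recordings[[1]])))
})

test_that("a 20-block plan yields the 100-trial session with per-block structure", {
  b <- simulateSession(quietPlan(n_blocks = 20, seed = 77))
  expect_equal(nTrials(b), 100)
  expect_equal(nrow(groundTruth(b)), 100)
  code7 <- vapply(b@recordings, function(r) sum(events(r)$code == 7), integer(1))
  expect_equal(sum(code7), 20)
  for (r in b@recordings[c(1, 20)])
    expect_equal(nrow(extractTrials(r)), 5)
  gt <- groundTruth(b)
  expect_true(all(gt$pn_ms >= 2500 & gt$pn_ms < 3500))
})

test_that("session drift perturbs amplitude, latency, and gains as specified", {
  plan <- sessionPlan(n_blocks = 1, seed = 5)
  expect_identical(applySessionDrift(plan, sessionDrift(1, 0, 0)), plan)
  expect_error(sessionDrift(amplitude_scale = 0), "amplitude_scale")

  shifted <- applySessionDrift(plan, sessionDrift(latency_shift_ms = 100))
  draws <- withr::with_seed(3, vapply(1:500, function(i)
    mrcpTemplate(shifted$mrcp, shifted$timeline)$true_pn_ms, numeric(1)))
  expect_lt(abs(mean(draws) - 3100), 20)

  quiet <- sessionPlan(n_blocks = 1, seed = 5, noise = noiseParams(0, 0, 0, 0),
                       mrcp = mrcpParams(pn_jitter_sd_ms = 0))
  doubled <- applySessionDrift(quiet, sessionDrift(amplitude_scale = 2))
  czMin <- function(p) min(eegData(simulateSession(p)@recordings[[1]])["Cz", ])
  expect_equal(czMin(doubled), 2 * czMin(quiet), tolerance = 1e-9)
})

test_that("pink background has a ~1/f power spectrum over 0.5-40 Hz", {
  n <- 300000                                  # a 10-minute draw at 500 Hz
  x <- withr::with_seed(8, mrcpbci:::pinkNoise(n, 500, 1))
  pw <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * 500 / n
  keep <- f >= 0.5 & f <= 40
  # bin log-log spectrum to tame periodogram variance, then fit the slope
  bins <- cut(log10(f[keep]), 30)
  lp <- tapply(log10(pw[keep]), bins, mean)
  lf <- tapply(log10(f[keep]), bins, mean)
  slope <- coef(lm(lp ~ lf))[[2]]
  expect_lt(abs(slope + 1), 0.2)
})
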