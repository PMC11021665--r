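#' @include recording.R
NULL

#' Trial timeline of the training protocol
#'
#' Each 10-s trial is: 3 s relax cue, 3 s preparation bar (the cue to move
#' arrives when the bar fills, 3000 ms after preparation start), movement
#' and 3 s hold, then the next trial. All durations in ms.
#'
#' @param relax_ms,prep_ms,hold_ms,trial_ms phase durations.
#' @param rate sampling rate (Hz).
#' @export
trialTimeline <- function(relax_ms = 3000, prep_ms = 3000, hold_ms = 3000,
                          trial_ms = 10000, rate = 500) {
  stopifnot(relax_ms > 0, prep_ms > 0, hold_ms > 0, rate > 0,
            relax_ms + prep_ms + hold_ms <= trial_ms)
  list(relax_ms = relax_ms, prep_ms = prep_ms, hold_ms = hold_ms,
       trial_ms = trial_ms, rate = rate)
}

#' MRCP template parameters
#'
#' The template mirrors the two components of a movement-related cortical
#' potential: a slow negative readiness drift starting `ramp_start_ms`
#' before the cue to move (cubic-smooth, monotone, reaching
#' `(1 - peak_frac)` of the full depth), plus a sharper negative
#' motor-potential peak (Gaussian, SD `peak_sd_ms`) centered on the
#' trial's peak negativity (PN), where the waveform attains exactly
#' `pn_amplitude`. After the PN the slow component rebounds to baseline
#' over `rebound_ms`. The PN latency is the cue time plus
#' truncated-normal jitter, so ground truth never leaves the +-500 ms
#' detection window.
#'
#' @param pn_amplitude peak negativity in uV (must be negative).
#' @param ramp_start_ms onset of the negative drift before the cue.
#' @param pn_jitter_sd_ms SD of the PN latency around the cue.
#' @param pn_jitter_trunc_ms truncation bound of the jitter (<= 500 so the
#'   PN stays inside the detection window).
#' @param rebound_ms return-to-baseline duration.
#' @param peak_frac fraction of the depth carried by the sharp peak.
#' @param peak_sd_ms temporal SD of the sharp peak.
#' @param latency_offset_ms systematic PN latency shift (used by
#'   [applySessionDrift()]).
#' @export
mrcpParams <- function(pn_amplitude = -10, ramp_start_ms = 1750,
                       pn_jitter_sd_ms = 150, pn_jitter_trunc_ms = 450,
                       rebound_ms = 1000, peak_frac = 0.35,
                       peak_sd_ms = 100, latency_offset_ms = 0) {
  stopifnot(pn_amplitude < 0, ramp_start_ms > 0,
            pn_jitter_sd_ms >= 0, rebound_ms > 0,
            pn_jitter_trunc_ms > 0, pn_jitter_trunc_ms <= 500,
            peak_frac >= 0, peak_frac < 1, peak_sd_ms > 0)
  list(pn_amplitude = pn_amplitude, ramp_start_ms = ramp_start_ms,
       pn_jitter_sd_ms = pn_jitter_sd_ms,
       pn_jitter_trunc_ms = pn_jitter_trunc_ms,
       rebound_ms = rebound_ms, peak_frac = peak_frac,
       peak_sd_ms = peak_sd_ms, latency_offset_ms = latency_offset_ms)
}

#' Background noise parameters
#'
#' 1/f ("pink") background, a 10 Hz alpha oscillation, and white sensor
#' noise. A fraction `pink_shared_frac` of the pink-noise variance is
#' spatially uniform across the scalp (volume-conducted far-field
#' activity, which a surface Laplacian cancels); the rest is independent
#' per channel. All values are uV (RMS for the noise terms, amplitude for
#' alpha).
#'
#' @param pink_rms total RMS of the 1/f background per channel.
#' @param alpha_amp amplitude of the 10 Hz oscillation (random phase per
#'   channel and trial).
#' @param sensor_white_rms RMS of white sensor noise.
#' @param pink_shared_frac fraction of pink variance shared across
#'   channels, in `[0, 1]`.
#' @export
noiseParams <- function(pink_rms = 4, alpha_amp = 0.5, sensor_white_rms = 0.5,
                        pink_shared_frac = 0.97) {
  stopifnot(pink_rms >= 0, alpha_amp >= 0, sensor_white_rms >= 0,
            pink_shared_frac >= 0, pink_shared_frac <= 1)
  list(pink_rms = pink_rms, alpha_amp = alpha_amp,
       sensor_white_rms = sensor_white_rms,
       pink_shared_frac = pink_shared_frac)
}

#' Scale all noise amplitudes by a common factor
#'
#' Convenience for signal-to-noise ladders: multiplies the pink, alpha and
#' sensor-noise amplitudes while keeping their proportions (and the shared
#' fraction) fixed.
#'
#' @param noise a [noiseParams()].
#' @param factor multiplicative factor (>= 0).
#' @export
scaleNoise <- function(noise, factor) {
  stopifnot(factor >= 0)
  noise$pink_rms <- noise$pink_rms * factor
  noise$alpha_amp <- noise$alpha_amp * factor
  noise$sensor_white_rms <- noise$sensor_white_rms * factor
  noise
}

#' Scalp topography of the simulated MRCP
#'
#' The template is projected to the scalp with a Gaussian gain falloff
#' around a midline-central focus (the lower-limb area of the motor
#' homunculus lies near the vertex, hence the Cz default).
#'
#' @param center channel label of the focus.
#' @param falloff_sd spatial Gaussian SD in montage head-circle units.
#' @export
topographyParams <- function(center = "Cz", falloff_sd = 0.25) {
  stopifnot(falloff_sd > 0)
  list(center = center, falloff_sd = falloff_sd)
}

#' Plan a synthetic session
#'
#' @param n_blocks number of 5-trial training blocks (20 blocks = the
#'   100-trial session scale of the protocol).
#' @param trials_per_block trials per block (5 under the protocol).
#' @param timeline a [trialTimeline()].
#' @param mrcp a [mrcpParams()].
#' @param noise a [noiseParams()].
#' @param topo a [topographyParams()].
#' @param seed RNG seed; simulation is a pure function of (plan, seed).
#' @param channel_gain_sd SD of per-channel multiplicative gain jitter,
#'   sampled once per session (session-drift mechanism).
#' @export
sessionPlan <- function(n_blocks = 20, trials_per_block = 5,
                        timeline = trialTimeline(), mrcp = mrcpParams(),
                        noise = noiseParams(), topo = topographyParams(),
                        seed = 1, channel_gain_sd = 0) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1)
  list(n_blocks = n_blocks, trials_per_block = trials_per_block,
       timeline = timeline, mrcp = mrcp, noise = noise, topo = topo,
       seed = seed, channel_gain_sd = channel_gain_sd)
}

#' Session-to-session drift
#'
#' @param amplitude_scale multiplies the template amplitude (> 0).
#' @param latency_shift_ms shifts the PN latency center.
#' @param gain_jitter_sd SD of per-channel gain jitter.
#' @export
sessionDrift <- function(amplitude_scale = 1, latency_shift_ms = 0,
                         gain_jitter_sd = 0) {
  if (amplitude_scale <= 0) stop("amplitude_scale must be > 0")
  list(amplitude_scale = amplitude_scale,
       latency_shift_ms = latency_shift_ms,
       gain_jitter_sd = gain_jitter_sd)
}

#' Apply drift to a session plan
#'
#' Returns a derived plan whose template amplitude, PN latency center, and
#' per-channel gains are perturbed as specified; an identity drift returns
#' the plan unchanged.
#'
#' @param plan a [sessionPlan()].
#' @param drift a [sessionDrift()].
#' @export
applySessionDrift <- function(plan, drift) {
  if (drift$amplitude_scale <= 0) stop("amplitude_scale must be > 0")
  plan$mrcp$pn_amplitude <- plan$mrcp$pn_amplitude * drift$amplitude_scale
  plan$mrcp$latency_offset_ms <- plan$mrcp$latency_offset_ms + drift$latency_shift_ms
  plan$channel_gain_sd <- plan$channel_gain_sd + drift$gain_jitter_sd
  plan
}

# truncated-normal PN jitter; additionally clamped so the PN stays inside
# the +-500 ms detection window around the cue even under latency drift
drawPnJitter <- function(mrcp) {
  lo <- max(-mrcp$pn_jitter_trunc_ms,
            -500 - mrcp$latency_offset_ms)
  hi <- min(mrcp$pn_jitter_trunc_ms,
            499 - mrcp$latency_offset_ms)
  if (lo >= hi) stop("latency offset leaves no room inside the detection window")
  if (mrcp$pn_jitter_sd_ms == 0) return(min(max(0, lo), hi))
  repeat {
    j <- rnorm(1, 0, mrcp$pn_jitter_sd_ms)
    if (j >= lo && j <= hi) return(j)
  }
}

#' Single-channel MRCP template
#'
#' Draws the trial's PN latency and evaluates the template over one trial.
#' The waveform is zero before `cue - ramp_start_ms`, decreases
#' monotonically (cubic smoothstep) to `pn_amplitude` exactly at the PN
#' sample, and rebounds smoothly to baseline over `rebound_ms`.
#'
#' @param params a [mrcpParams()].
#' @param timeline a [trialTimeline()].
#' @return list with `waveform` (one trial of samples) and `true_pn_ms`
#'   (PN latency in ms relative to preparation start). Uses the current
#'   RNG state; seed via [sessionPlan()] / `set.seed()` for reproducibility.
#' @export
mrcpTemplate <- function(params, timeline = trialTimeline()) {
  rate <- timeline$rate
  n <- msToSamples(timeline$trial_ms, rate)
  cueRel <- timeline$prep_ms                       # ms relative to prep start
  pnRel <- cueRel + params$latency_offset_ms + drawPnJitter(params)
  # absolute trial time of the anchors (prep starts after the relax phase)
  cueAbs <- timeline$relax_ms + cueRel
  pnAbs <- timeline$relax_ms + pnRel
  rampAbs <- cueAbs - params$ramp_start_ms
  t <- (seq_len(n) - 1) * 1000 / rate
  w <- numeric(n)
  smoothstep <- function(u) u * u * (3 - 2 * u)
  slowA <- params$pn_amplitude * (1 - params$peak_frac)
  ramp <- t >= rampAbs & t < pnAbs
  # convex (cubic) ramp: shallow early drift accelerating toward the PN,
  # the classic readiness-potential shape
  w[ramp] <- slowA * ((t[ramp] - rampAbs) / (pnAbs - rampAbs))^3
  reb <- t >= pnAbs & t < pnAbs + params$rebound_ms
  w[reb] <- slowA * (1 - smoothstep((t[reb] - pnAbs) / params$rebound_ms))
  if (params$peak_frac > 0) {
    peakA <- params$pn_amplitude * params$peak_frac
    near <- abs(t - pnAbs) <= 4 * params$peak_sd_ms & t >= rampAbs
    w[near] <- w[near] +
      peakA * exp(-(t[near] - pnAbs)^2 / (2 * params$peak_sd_ms^2))
  }
  # pin the minimum to the PN sample exactly
  w[msToSamples(pnAbs, rate) + 1L] <- params$pn_amplitude
  list(waveform = w, true_pn_ms = pnRel)
}

# 1/f-amplitude noise via spectral shaping of white noise
pinkNoise <- function(n, rate, rms) {
  if (rms == 0) return(numeric(n))
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))                        # bin 1 is DC
  f <- pmin(f, n - f + 1)                          # mirror upper half
  shape <- 1 / sqrt(f)
  shape[1] <- 0                                    # remove DC
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x * rms / sd(x)
}

# per-channel topographic gains for the template projection
topoGains <- function(montage, topo, gainJitter = NULL) {
  d <- montageDistances(montage, topo$center)
  g <- exp(-d^2 / (2 * topo$falloff_sd^2))
  if (!is.null(gainJitter)) g <- g * gainJitter
  g
}

#' Simulate a single trial
#'
#' One 10-s, 64-channel segment: the MRCP template projected over the
#' scalp plus 1/f background, alpha, and sensor noise. Uses the current
#' RNG state (the per-trial randomness); [simulateSession()] seeds it from
#' the plan.
#'
#' @param plan a [sessionPlan()].
#' @param montage the montage to simulate (default [standardMontage()]).
#' @param gainJitter optional per-channel gain factors (session drift).
#' @return list with `data` (channels x samples), `events` (trial-relative
#'   trigger rows: code 8 at 0, code 6 at preparation start), and
#'   `truth` (`pn_ms`, `amplitude`).
#' @export
simulateTrial <- function(plan, montage = standardMontage(), gainJitter = NULL) {
  tl <- plan$timeline
  tmpl <- mrcpTemplate(plan$mrcp, tl)
  gains <- topoGains(montage, plan$topo, gainJitter)
  nCh <- length(montage@labels)
  n <- length(tmpl$waveform)
  data <- outer(gains, tmpl$waveform)
  ns <- plan$noise
  tSec <- (seq_len(n) - 1) / tl$rate
  sharedRms <- ns$pink_rms * sqrt(ns$pink_shared_frac)
  localRms <- ns$pink_rms * sqrt(1 - ns$pink_shared_frac)
  shared <- if (sharedRms > 0) pinkNoise(n, tl$rate, sharedRms) else numeric(n)
  for (c in seq_len(nCh)) {
    ch <- shared
    if (localRms > 0) ch <- ch + pinkNoise(n, tl$rate, localRms)
    if (ns$alpha_amp > 0)
      ch <- ch + ns$alpha_amp * sin(2 * pi * 10 * tSec + runif(1, 0, 2 * pi))
    if (ns$sensor_white_rms > 0) ch <- ch + rnorm(n, 0, ns$sensor_white_rms)
    data[c, ] <- data[c, ] + ch
  }
  rownames(data) <- montage@labels
  prepSample <- msToSamples(tl$relax_ms, tl$rate)
  list(data = data,
       events = data.frame(code = c(TRIG_TRIAL_START, TRIG_PREP_START),
                           sample = c(0L, prepSample)),
       truth = data.frame(pn_ms = tmpl$true_pn_ms,
                          amplitude = plan$mrcp$pn_amplitude *
                            gains[plan$topo$center]))
}

#' Simulate a full session
#'
#' Generates `n_blocks` block recordings of `trials_per_block` trials each,
#' with protocol trigger streams (8 = trial start, 6 = prep start, 7 closes
#' each block) and a ground-truth table of true PN latencies. Deterministic
#' given the plan (which includes the seed).
#'
#' @param plan a [sessionPlan()].
#' @param sessionId identifier stored in the bundle.
#' @return a [SessionBundle-class] with ground truth.
#' @examples
#' plan <- sessionPlan(n_blocks = 2, seed = 7)
#' b <- simulateSession(plan)
#' nTrials(b)
#' @export
simulateSession <- function(plan, sessionId = "synthetic") {
  montage <- standardMontage()
  withSeed(plan$seed, {
    gainJitter <- if (plan$channel_gain_sd > 0)
      pmax(0.1, 1 + rnorm(length(montage@labels), 0, plan$channel_gain_sd))
    else rep(1, length(montage@labels))
    names(gainJitter) <- montage@labels
    tl <- plan$timeline
    nTrialSamp <- msToSamples(tl$trial_ms, tl$rate)
    recs <- vector("list", plan$n_blocks)
    gt <- NULL
    for (b in seq_len(plan$n_blocks)) {
      mats <- vector("list", plan$trials_per_block)
      ev <- NULL
      for (k in seq_len(plan$trials_per_block)) {
        tr <- simulateTrial(plan, montage, gainJitter)
        mats[[k]] <- tr$data
        evk <- tr$events
        evk$sample <- evk$sample + (k - 1L) * nTrialSamp
        ev <- rbind(ev, evk)
        gt <- rbind(gt, data.frame(block = b, trial = k,
                                   pn_ms = tr$truth$pn_ms,
                                   amplitude = tr$truth$amplitude))
      }
      blockData <- do.call(cbind, mats)
      ev <- rbind(ev, data.frame(code = TRIG_BLOCK_END,
                                 sample = ncol(blockData) - 1L))
      recs[[b]] <- eegRecording(blockData, tl$rate, montage, ev)
    }
    sessionBundle(recs, sessionId, gt, plan)
  })
}
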