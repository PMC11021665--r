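#' @include harness.R transfer.R evaluation.R simulate.R
NULL

#' Default run configuration
#'
#' Nested keys for every pipeline stage. Unknown keys are rejected by
#' [loadConfig()]; every pipeline run writes the resolved configuration
#' next to its outputs.
#'
#' @return nested named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    seed = 1,
    out_dir = "mrcpbci-out",
    simulator = list(n_blocks = 20, trials_per_block = 5,
                     pn_amplitude = -10, pn_jitter_sd_ms = 150,
                     noise_scale = 1, amplitude_scale = 1,
                     latency_shift_ms = 0, gain_jitter_sd = 0),
    filter = list(low_hz = 0.05, high_hz = 10, order = 2,
                  mode = "offline_zero_phase"),
    channels = list(sensorimotor = sensorimotorChannels()),
    calibration = list(n_trials = 25, scheme = "time_based", threshold_k = 2),
    detector = list(kind = "lstm", input_dim = 20, hidden = 100,
                    epochs = 100, batch = 8, mlp_hidden = c(20, 20, 20),
                    mlp_epochs = 50, mlp_lr = 0.01),
    harness = list(tick_ms = 50, packet_len_samples = 25,
                   trigger_fraction = 0.8, fallback_enabled = TRUE,
                   fn_mode = "default"),
    transfer = list(finetune_trials = 25, hidden = 100, epochs = 100),
    evaluation = list(split = 0.5, seeds = 1:5)
  )
}

mergeConfig <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown config key: ", paste(c(path, key), collapse = "."))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("config key must be a mapping: ", paste(c(path, key), collapse = "."))
      defaults[[key]] <- mergeConfig(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validateConfig <- function(cfg) {
  rate <- 500
  if (cfg$filter$high_hz >= rate / 2)
    stop(sprintf("config key filter.high_hz: %g is not below the Nyquist frequency (%g)",
                 cfg$filter$high_hz, rate / 2))
  if (cfg$filter$low_hz <= 0 || cfg$filter$low_hz >= cfg$filter$high_hz)
    stop("config key filter.low_hz: must satisfy 0 < low < high")
  if (!cfg$detector$kind %in% c("threshold", "avgpn", "mlp", "lstm"))
    stop("config key detector.kind: unknown detector")
  if (cfg$harness$trigger_fraction <= 0 || cfg$harness$trigger_fraction > 1)
    stop("config key harness.trigger_fraction: must be in (0, 1]")
  cfg
}

#' Load a YAML run configuration
#'
#' Missing keys take their defaults; unknown keys and out-of-range values
#' are rejected with the offending key named.
#'
#' @param path YAML file; an empty or missing body yields all defaults.
#' @return validated nested configuration list.
#' @export
loadConfig <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validateConfig(mergeConfig(defaultConfig(), user))
}

#' @rdname loadConfig
#' @param cfg configuration list to write.
#' @export
saveConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# -------------------------------------------------------------- logging

logMessage <- function(level = "INFO", ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...)))
}

# hash of the scientific configuration; the output location is excluded
# so identical runs into different directories share a hash
configHash <- function(cfg) {
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveConfig(cfg, tmp)
  unname(tools::md5sum(tmp))
}

# -------------------------------------------------------------- pipeline

planFromConfig <- function(cfg) {
  sim <- cfg$simulator
  plan <- sessionPlan(
    n_blocks = sim$n_blocks, trials_per_block = sim$trials_per_block,
    mrcp = mrcpParams(pn_amplitude = sim$pn_amplitude,
                      pn_jitter_sd_ms = sim$pn_jitter_sd_ms),
    noise = scaleNoise(noiseParams(), sim$noise_scale),
    seed = deriveSeed(cfg$seed, "simulate"))
  drift <- sessionDrift(amplitude_scale = sim$amplitude_scale,
                        latency_shift_ms = sim$latency_shift_ms,
                        gain_jitter_sd = sim$gain_jitter_sd)
  applySessionDrift(plan, drift)
}

filterFromConfig <- function(cfg, mode = cfg$filter$mode) {
  filterSpec(cfg$filter$low_hz, cfg$filter$high_hz, cfg$filter$order, mode)
}

harnessFromConfig <- function(cfg) {
  harnessSpec(tick_ms = cfg$harness$tick_ms,
              packet_len_samples = cfg$harness$packet_len_samples,
              trigger_fraction = cfg$harness$trigger_fraction,
              fallback_enabled = cfg$harness$fallback_enabled,
              fn_mode = cfg$harness$fn_mode)
}

detectorFromConfig <- function(cfg, cal, dataset) {
  kind <- cfg$detector$kind
  seed <- deriveSeed(cfg$seed, "train")
  switch(kind,
    threshold = thresholdDetector(cal@thresholdValue, cal@thresholdK),
    avgpn = averagePnDetector(cal@avgPnMs),
    mlp = trainMLP(dataset, mlpConfig(hidden = cfg$detector$mlp_hidden,
                                      epochs = cfg$detector$mlp_epochs,
                                      lr = cfg$detector$mlp_lr,
                                      batch = cfg$detector$batch,
                                      seed = seed)),
    lstm = trainLSTM(dataset, lstmConfig(input_dim = cfg$detector$input_dim,
                                         hidden = cfg$detector$hidden,
                                         epochs = cfg$detector$epochs,
                                         batch = cfg$detector$batch,
                                         seed = seed)))
}

#' Run the full pipeline: simulate, calibrate, train, run, evaluate
#'
#' Produces, under `cfg$out_dir`: the session bundle, calibration JSON,
#' detector model, session report (JSON + per-trial CSV), evaluation
#' metrics JSON, and the resolved configuration. Outputs are identical for
#' identical (config, seed).
#'
#' @param cfg configuration from [loadConfig()] / [defaultConfig()].
#' @param verbose log stage progress.
#' @return invisibly, a list with the in-memory stage outputs.
#' @export
runPipeline <- function(cfg = defaultConfig(), verbose = TRUE) {
  cfg <- validateConfig(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(cfg)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)), call. = FALSE))
    logMessage("INFO", sprintf("stage %s done in %.1f s", name,
                               proc.time()[["elapsed"]] - t0),
               verbose = verbose)
    out
  }
  logMessage("INFO", sprintf("run start: seed %s, config %s", cfg$seed, hash),
             verbose = verbose)
  saveConfig(cfg, file.path(cfg$out_dir, "config.yaml"))

  bundle <- stage("simulate", {
    b <- simulateSession(planFromConfig(cfg))
    writeBundle(b, file.path(cfg$out_dir, "bundle.rds"))
    b
  })
  calOut <- stage("calibrate", {
    out <- calibrateSession(bundle, nTrials = NULL,
                            scheme = labelingScheme(cfg$calibration$scheme),
                            k = cfg$calibration$threshold_k,
                            spec = filterFromConfig(cfg, "offline_zero_phase"))
    cal <- out$calibration
    jsonlite::write_json(
      list(pn_times_ms = cal@pnTimesMs, avg_pn_ms = cal@avgPnMs,
           threshold_uv = cal@thresholdValue, threshold_k = cal@thresholdK,
           scheme = cal@scheme, seed = cfg$seed, config_hash = hash),
      file.path(cfg$out_dir, "calibration.json"),
      auto_unbox = TRUE, digits = NA)
    out
  })
  trained <- stage("train", {
    nAll <- nTrials(calOut$dataset)
    nTrain <- floor(nAll * cfg$evaluation$split)
    if (nTrain < 1 || nTrain >= nAll)
      stop(sprintf("evaluation.split (%g) leaves no training or test trials",
                   cfg$evaluation$split))
    trainSet <- subsetEpochs(calOut$dataset, seq_len(nTrain))
    testSet <- subsetEpochs(calOut$dataset, (nTrain + 1):nAll)
    m <- detectorFromConfig(cfg, calOut$calibration, trainSet)
    saveDetector(m, file.path(cfg$out_dir, "model.rds"))
    list(model = m, trainSet = trainSet, testSet = testSet)
  })
  model <- trained$model
  testSet <- trained$testSet
  report <- stage("run", {
    rep <- runSession(model, bundle, harnessFromConfig(cfg),
                      filter = filterFromConfig(cfg, "causal"))
    write.csv(rep@trials, file.path(cfg$out_dir, "session_trials.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(accuracy_pct = rep@accuracy, fp_pct = rep@fpRate,
           fn_pct = rep@fnRate, counts = as.list(rep@counts),
           seed = cfg$seed, config_hash = hash),
      file.path(cfg$out_dir, "session_report.json"),
      auto_unbox = TRUE, digits = NA)
    rep
  })
  metrics <- stage("evaluate", {
    met <- list(seed = cfg$seed, config_hash = hash)
    if (is(model, "MLPDetector") || is(model, "LSTMDetector"))
      met$sample_accuracy <- heldOutAccuracy(model, testSet)
    done <- report@trials$category %in% c("true_positive", "false_positive")
    if (any(done) && nrow(bundle@groundTruth)) {
      errs <- detectionError(report@trials$time_ms[done],
                             bundle@groundTruth$pn_ms[done])
      met$error_mean_ms <- errs$mean
      met$error_sd_ms <- errs$sd
      met$error_rmse_ms <- errs$rmse
    }
    jsonlite::write_json(met, file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    met
  })
  logMessage("INFO", sprintf("run summary: seed %s, config %s, %d trials, accuracy %.1f%%",
                             cfg$seed, hash, nrow(report@trials),
                             report@accuracy),
             verbose = verbose)
  invisible(list(bundle = bundle, calibration = calOut$calibration,
                 dataset = calOut$dataset, model = model, report = report,
                 metrics = metrics))
}
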