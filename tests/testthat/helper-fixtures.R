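# Shared fixtures: small session plans and programmatic writers for the
# standard EEG file formats (files are generated at test time).

quietPlan <- function(n_blocks = 2, seed = 101, ...) {
  sessionPlan(n_blocks = n_blocks, seed = seed, ...)
}

noiselessPlan <- function(n_blocks = 1, seed = 11, jitter = 0) {
  sessionPlan(n_blocks = n_blocks, seed = seed,
              mrcp = mrcpParams(pn_jitter_sd_ms = jitter),
              noise = noiseParams(0, 0, 0, 0))
}

# small detector configs so unit tests stay fast; the acceptance suite
# exercises the full-size defaults
tinyLstm <- function(seed = 1, ...) {
  lstmConfig(hidden = 16, epochs = 10, seed = seed, ...)
}

tinyMlp <- function(seed = 1, ...) {
  mlpConfig(hidden = c(8, 8), epochs = 8, seed = seed, ...)
}

# a labeled dataset from a small synthetic session (cached per session)
makeDataset <- function(n_blocks = 3, seed = 101,
                        scheme = labelingScheme("time_based")) {
  b <- simulateSession(quietPlan(n_blocks = n_blocks, seed = seed))
  calibrateSession(b, scheme = scheme)
}

padTo <- function(s, n) {
  s <- substr(s, 1, n)
  formatC(s, width = -n)   # left-justified, blank padded
}

# Minimal EDF(+) writer: int16 data records plus an "EDF Annotations"
# signal carrying the trigger events as stimulus TALs.
writeEdfFixture <- function(path, data, rate, events = NULL,
                            labels = rownames(data)) {
  nCh <- nrow(data)
  nSamples <- ncol(data)
  stopifnot(nSamples %% rate == 0)
  nRec <- nSamples / rate
  annBytes <- 120L
  ns <- nCh + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(padTo("0", 8), con, eos = NULL)
  writeChar(padTo("X X X X", 80), con, eos = NULL)          # patient
  writeChar(padTo("Startdate X X X X", 80), con, eos = NULL)
  writeChar(padTo("01.01.20", 8), con, eos = NULL)
  writeChar(padTo("00.00.00", 8), con, eos = NULL)
  writeChar(padTo(as.character(256 * (1 + ns)), 8), con, eos = NULL)
  writeChar(padTo("EDF+C", 44), con, eos = NULL)
  writeChar(padTo(as.character(nRec), 8), con, eos = NULL)
  writeChar(padTo("1", 8), con, eos = NULL)                  # 1 s records
  writeChar(padTo(as.character(ns), 4), con, eos = NULL)
  sigField <- function(vals, width)
    for (v in vals) writeChar(padTo(v, width), con, eos = NULL)
  sigField(c(labels, "EDF Annotations"), 16)
  sigField(rep("", ns), 80)                                  # transducer
  sigField(c(rep("uV", nCh), ""), 8)                         # phys dim
  sigField(c(rep("-3276.8", nCh), "-1"), 8)                  # phys min
  sigField(c(rep("3276.7", nCh), "1"), 8)                    # phys max
  sigField(c(rep("-32768", nCh), "-32768"), 8)               # dig min
  sigField(c(rep("32767", nCh), "32767"), 8)                 # dig max
  sigField(rep("", ns), 80)                                  # prefiltering
  sigField(c(rep(as.character(rate), nCh), as.character(annBytes / 2)), 8)
  sigField(rep("", ns), 32)                                  # reserved
  dig <- round(data * 10)                                    # 0.1 uV/bit
  stopifnot(all(abs(dig) <= 32767))
  for (r in seq_len(nRec)) {
    cols <- ((r - 1) * rate + 1):(r * rate)
    for (ch in seq_len(nCh))
      writeBin(as.integer(dig[ch, cols]), con, size = 2, endian = "little")
    tal <- sprintf("+%d\x14\x14", r - 1)
    if (!is.null(events)) {
      inRec <- events[events$sample >= (r - 1) * rate &
                      events$sample < r * rate, , drop = FALSE]
      for (i in seq_len(nrow(inRec)))
        tal <- paste0(tal, sprintf("+%.6f\x150\x14S %d\x14",
                                   inRec$sample[i] / rate, inRec$code[i]))
    }
    raw <- charToRaw(tal)
    stopifnot(length(raw) <= annBytes)
    writeBin(c(raw, raw(annBytes - length(raw))), con)
  }
  invisible(path)
}

# Minimal BrainVision writer (multiplexed IEEE_FLOAT_32 + stimulus markers)
writeBrainVisionFixture <- function(dir, name, data, rate, events = NULL,
                                    labels = rownames(data)) {
  vhdr <- file.path(dir, paste0(name, ".vhdr"))
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", name, ".eeg"),
    paste0("MarkerFile=", name, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(data)),
    paste0("SamplingInterval=", format(1e6 / rate, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(data)), labels)
  ), vhdr)
  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", name, ".eeg"),
           "[Marker Infos]",
           "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (!is.null(events))
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                          seq_len(nrow(events)) + 1L, events$code,
                          events$sample + 1L))
  writeLines(mrk, file.path(dir, paste0(name, ".vmrk")))
  con <- file(file.path(dir, paste0(name, ".eeg")), "wb")
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  close(con)
  vhdr
}
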