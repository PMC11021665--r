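#' @include recording.R
NULL

# Accept both numeric codes and amplifier-style stimulus labels ("S  6",
# "Stimulus/S6", "6"); returns NA for unparseable descriptions.
parseTriggerCode <- function(text) {
  m <- regmatches(text, regexpr("[0-9]+[[:space:]]*$", text))
  out <- rep(NA_integer_, length(text))
  has <- lengths(regmatches(text, gregexpr("[0-9]+[[:space:]]*$", text))) > 0
  out[has] <- as.integer(trimws(m))
  out
}

#' Read an EEG recording from EDF, BrainVision, or the internal bundle
#'
#' EDF(+) files are read record-by-record with digital-to-physical scaling;
#' trigger events come from the "EDF Annotations" signal. BrainVision
#' triples (.vhdr/.vmrk/.eeg) support multiplexed INT_16 and IEEE_FLOAT_32
#' data; marker positions (1-based in .vmrk) become 0-based sample indices.
#' Amplitudes are converted to microvolts in both cases.
#'
#' @param path file path (.edf, .vhdr, or a bundle .rds).
#' @param format one of "edf", "brainvision", "bundle"; inferred from the
#'   file extension by default.
#' @param requireEvents error if the file carries no trigger/annotation
#'   channel (default TRUE).
#' @return an [EEGRecording-class].
#' @export
readRecording <- function(path, format = c("auto", "edf", "brainvision", "bundle"),
                          requireEvents = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision", rds = "bundle",
                     stop("cannot infer format from extension: ", ext))
  }
  switch(format,
         edf = readEdf(path, requireEvents),
         brainvision = readBrainVision(path, requireEvents),
         bundle = {
           x <- readBundle(path)
           if (!is(x, "EEGRecording")) stop("bundle does not hold a recording")
           x
         })
}

readEdf <- function(path, requireEvents = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) stop("not an EDF file (short header): ", path)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  nRecords <- as.integer(fld(hdr, 237, 8))
  recDur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1) stop("not an EDF file (bad signal count): ", path)
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  # per-signal header block offsets (bytes per signal, fields stored
  # field-by-field across all signals)
  off <- c(label = 0, transducer = 16, dim = 96, physMin = 104, physMax = 112,
           digMin = 120, digMax = 128, prefilt = 136, nsamp = 216, reserved = 224)
  pick <- function(name, len) {
    start <- off[[name]] * ns
    vapply(seq_len(ns), function(i)
      trimws(substr(sig, start + (i - 1) * len + 1, start + i * len)),
      character(1))
  }
  labels <- pick("label", 16)
  dims <- pick("dim", 8)
  physMin <- as.numeric(pick("physMin", 8)); physMax <- as.numeric(pick("physMax", 8))
  digMin <- as.numeric(pick("digMin", 8));  digMax <- as.numeric(pick("digMax", 8))
  nsamp <- as.integer(pick("nsamp", 8))
  isAnn <- grepl("^EDF Annotations", labels)
  dataIdx <- which(!isAnn)
  if (requireEvents && !any(isAnn))
    stop("no events: EDF file has no annotation channel: ", path)
  rate <- nsamp[dataIdx] / recDur
  if (length(unique(rate)) > 1) stop("mixed sampling rates are not supported")
  rate <- rate[1]
  gain <- (physMax - physMin) / (digMax - digMin)
  unitScale <- ifelse(grepl("^mV$", dims, ignore.case = TRUE), 1000,
                      ifelse(grepl("^V$", dims), 1e6, 1))
  chunks <- vector("list", nRecords)
  annText <- character(0)
  for (r in seq_len(nRecords)) {
    rec <- matrix(NA_real_, length(dataIdx), max(nsamp[dataIdx]))
    di <- 1L
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                     endian = "little")
      if (isAnn[i]) {
        bytes <- writeBin(as.integer(raw), raw(), size = 2, endian = "little")
        annText <- c(annText, rawToChar(bytes[bytes != as.raw(0)]))
      } else {
        rec[di, seq_len(nsamp[i])] <-
          ((raw - digMin[i]) * gain[i] + physMin[i]) * unitScale[i]
        di <- di + 1L
      }
    }
    chunks[[r]] <- rec
  }
  data <- do.call(cbind, chunks)
  rownames(data) <- labels[dataIdx]
  events <- parseEdfAnnotations(paste(annText, collapse = ""), rate)
  if (requireEvents && !nrow(events))
    stop("no events: EDF annotation channel holds no trigger annotations: ", path)
  m <- validateMontage(labels[dataIdx])
  eegRecording(data, rate, m, events)
}

# Time-stamped annotation lists: "+onset[\x15duration]\x14text\x14..."
parseEdfAnnotations <- function(txt, rate) {
  tals <- strsplit(txt, "\x14\x14|\x14(?=[+-])", perl = TRUE)[[1]]
  code <- integer(0); sample <- integer(0)
  for (tal in tals) {
    parts <- strsplit(tal, "\x14")[[1]]
    if (length(parts) < 2) next            # bare timestamp TAL
    onset <- as.numeric(strsplit(parts[1], "\x15")[[1]][1])
    if (is.na(onset)) next
    for (text in parts[-1]) {
      cd <- parseTriggerCode(text)
      if (!is.na(cd)) {
        code <- c(code, cd)
        sample <- c(sample, as.integer(round(onset * rate)))
      }
    }
  }
  data.frame(code = code, sample = sample)
}

readBrainVision <- function(vhdrPath, requireEvents = TRUE) {
  ini <- readBrainVisionIni(vhdrPath)
  common <- ini[["Common Infos"]]
  if (is.null(common)) stop("not a BrainVision header: ", vhdrPath)
  dirn <- dirname(vhdrPath)
  nCh <- as.integer(common[["NumberOfChannels"]])
  rate <- 1e6 / as.numeric(common[["SamplingInterval"]])
  orientation <- toupper(common[["DataOrientation"]] %||% "MULTIPLEXED")
  if (orientation != "MULTIPLEXED")
    stop("only MULTIPLEXED BrainVision data are supported")
  fmt <- toupper(ini[["Binary Infos"]][["BinaryFormat"]] %||% "INT_16")
  chinfo <- ini[["Channel Infos"]]
  labels <- character(nCh); res <- rep(1, nCh)
  for (i in seq_len(nCh)) {
    parts <- strsplit(chinfo[[paste0("Ch", i)]], ",")[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[i] <- as.numeric(parts[3])
  }
  eegPath <- file.path(dirn, common[["DataFile"]])
  nBytes <- file.size(eegPath)
  conE <- file(eegPath, "rb"); on.exit(close(conE), add = TRUE)
  if (fmt == "INT_16") {
    n <- nBytes / 2
    raw <- readBin(conE, "integer", n = n, size = 2, signed = TRUE, endian = "little")
  } else if (fmt == "IEEE_FLOAT_32") {
    n <- nBytes / 4
    raw <- readBin(conE, "numeric", n = n, size = 4, endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  data <- matrix(raw, nrow = nCh) * res
  rownames(data) <- labels
  events <- data.frame(code = integer(), sample = integer())
  mrkFile <- common[["MarkerFile"]]
  if (!is.null(mrkFile) && file.exists(file.path(dirn, mrkFile))) {
    mrk <- readBrainVisionIni(file.path(dirn, mrkFile))[["Marker Infos"]]
    for (key in names(mrk)) {
      parts <- strsplit(mrk[[key]], ",")[[1]]
      if (length(parts) < 3 || parts[1] != "Stimulus") next
      cd <- parseTriggerCode(parts[2])
      if (is.na(cd)) next
      events <- rbind(events,
                      data.frame(code = cd, sample = as.integer(parts[3]) - 1L))
    }
  } else if (requireEvents) {
    stop("no events: BrainVision marker file missing for ", vhdrPath)
  }
  if (requireEvents && !nrow(events))
    stop("no events: BrainVision marker file holds no stimulus markers")
  eegRecording(data, rate, validateMontage(labels), events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal INI parser for .vhdr/.vmrk (comments ';', sections '[...]')
readBrainVisionIni <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); section <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln) && !is.null(section)) {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}
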