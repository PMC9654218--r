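#' Read a European Data Format (EDF) recording
#'
#' Minimal EDF import for continuous EEG: parses the fixed 256-byte header
#' and the per-signal header block, reads the 16-bit little-endian data
#' records and rescales digital values to physical units using each
#' signal's physical/digital ranges.  Values are converted to microvolts
#' when the physical dimension is V or mV; dimensionless or uV signals are
#' taken as microvolts.
#'
#' All signals must share one sampling rate (the common case for scalp
#' EEG); mixed-rate files are refused as an unsupported dialect.
#'
#' @param path path to an EDF file.
#' @param subjectId subject id for the returned recording; defaults to the
#'   file's local patient identification field (first token).
#' @return an [EEGRecording-class].
#' @seealso [writeEDF()]
#' @export
readEDF <- function(path, subjectId = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  readStr <- function(nbytes) {
    raw <- readBin(con, "raw", n = nbytes)
    if (length(raw) < nbytes) stop("truncated EDF header")
    trimws(rawToChar(raw))
  }
  version <- readStr(8L)
  if (version != "0")
    stop("not an EDF file (header version field is not '0')")
  patient <- readStr(80L)
  readStr(80L)                       # recording identification
  readStr(8L); readStr(8L)           # start date, time
  headerBytes <- as.integer(readStr(8L))
  readStr(44L)                       # reserved
  nRecords <- as.integer(readStr(8L))
  recordDurS <- as.numeric(readStr(8L))
  nSignals <- as.integer(readStr(4L))
  if (is.na(nSignals) || nSignals < 1L)
    stop("EDF file declares no signals")

  field <- function(nbytes, what = "character") {
    vapply(seq_len(nSignals), function(i) readStr(nbytes), character(1))
  }
  labels <- field(16L)
  field(80L)                         # transducer
  physDim <- field(8L)
  physMin <- as.numeric(field(8L))
  physMax <- as.numeric(field(8L))
  digMin <- as.numeric(field(8L))
  digMax <- as.numeric(field(8L))
  field(80L)                         # prefiltering
  samplesPerRecord <- as.integer(field(8L))
  field(32L)                         # reserved

  if (any(is.na(c(physMin, physMax, digMin, digMax, samplesPerRecord))))
    stop("malformed EDF signal headers")
  if (length(unique(samplesPerRecord)) != 1L)
    stop("signals with mismatched sampling rates are not supported")
  spr <- samplesPerRecord[1L]
  fs <- spr / recordDurS

  seek(con, where = headerBytes, origin = "start")
  need <- nRecords * nSignals * spr
  dig <- readBin(con, "integer", n = need, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(dig) < need)
    stop("truncated EDF data section (expected ", need, " samples, got ",
         length(dig), ")")

  # records are interleaved: [rec1: sig1 block, sig2 block, ...][rec2: ...]
  dim(dig) <- c(spr, nSignals, nRecords)
  signal <- matrix(0, nSignals, spr * nRecords)
  gain <- (physMax - physMin) / (digMax - digMin)
  unitScale <- vapply(physDim, function(u) {
    switch(tolower(u), "v" = 1e6, "mv" = 1e3, 1)
  }, numeric(1))
  for (s in seq_len(nSignals)) {
    x <- as.vector(dig[, s, ])
    signal[s, ] <- (physMin[s] + (x - digMin[s]) * gain[s]) * unitScale[s]
  }
  if (is.null(subjectId))
    subjectId <- if (nzchar(patient)) strsplit(patient, " ")[[1L]][1L] else "S1"
  eegRecording(signal, fs = fs, channelNames = labels, subjectId = subjectId)
}

#' Write an EEGRecording as an EDF file
#'
#' Companion writer used to produce EDF fixtures and to export simulated
#' recordings.  Samples are quantised to the full 16-bit digital range
#' over each channel's physical range (or a supplied symmetric range), so
#' the round-trip error is bounded by half a quantisation step.
#'
#' @param rec an [EEGRecording-class] (microvolts).
#' @param path output path.
#' @param physicalRange optional positive number `r`: use \[-r, r\]
#'   microvolts for every channel; default is each channel's own range.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path, physicalRange = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  nSignals <- nChannels(rec)
  fs <- rec@fs
  recordDurS <- 1
  spr <- as.integer(round(fs * recordDurS))
  nRecords <- ncol(rec@signal) %/% spr
  if (nRecords < 1L) stop("recording shorter than one 1 s EDF record")
  x <- rec@signal[, seq_len(nRecords * spr), drop = FALSE]

  if (is.null(physicalRange)) {
    physMax <- apply(x, 1, function(v) max(abs(range(v)), 1))
  } else physMax <- rep(physicalRange, nSignals)
  # round-trip the range through its 8-char header encoding so that the
  # quantisation gain matches what a reader will recover
  physMax <- as.numeric(substr(formatC(physMax, format = "g", digits = 6), 1L, 8L))
  physMin <- -physMax
  digMax <- 32767; digMin <- -32768

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  pad <- function(v, width) {
    s <- formatC(as.character(v), width = -width)
    s <- substr(s, 1L, width)
    writeChar(paste(s, collapse = ""), con, eos = NULL)
  }
  headerBytes <- 256L + 256L * nSignals
  pad("0", 8L)
  pad(rec@subjectId, 80L)
  pad("simulated", 80L)
  pad("01.01.26", 8L); pad("00.00.00", 8L)
  pad(headerBytes, 8L)
  pad("", 44L)
  pad(nRecords, 8L)
  pad(format(recordDurS), 8L)
  pad(nSignals, 4L)
  for (nm in rec@channelNames) pad(nm, 16L)
  for (i in seq_len(nSignals)) pad("simulated", 80L)
  for (i in seq_len(nSignals)) pad("uV", 8L)
  for (v in physMin) pad(formatC(v, format = "g", digits = 6), 8L)
  for (v in physMax) pad(formatC(v, format = "g", digits = 6), 8L)
  for (i in seq_len(nSignals)) pad(digMin, 8L)
  for (i in seq_len(nSignals)) pad(digMax, 8L)
  for (i in seq_len(nSignals)) pad("", 80L)
  for (i in seq_len(nSignals)) pad(spr, 8L)
  for (i in seq_len(nSignals)) pad("", 32L)

  gain <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRecords)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(nSignals)) {
      dig <- round(digMin + (x[s, idx] - physMin[s]) * gain[s])
      dig <- pmin(pmax(dig, digMin), digMax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
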