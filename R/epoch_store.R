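#' Save an epoch set as a manifest-plus-binary epoch store
#'
#' Writes a directory holding `manifest.json` (plain text: shapes,
#' sampling rate, window, label set, per-epoch labels and subject ids,
#' byte order, checksum) and `epochs.bin`, the sample data as
#' little-endian 32-bit floats.  The binary layout is epoch-major:
#' for epoch i, channel c, the `windowSamples` samples are contiguous
#' with the sample index varying fastest, then the channel, then the
#' epoch.  The round trip is lossless at 32-bit precision.
#'
#' @param es an [EEGEpochSet-class].
#' @param dir target directory (created if needed).
#' @return the manifest path, invisibly.
#' @seealso [loadEpochStore()]
#' @export
saveEpochStore <- function(es, dir) {
  stopifnot(is(es, "EEGEpochSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  binPath <- file.path(dir, "epochs.bin")
  d <- dim(es@epochs)
  # (epoch, channel, sample) -> sample fastest, then channel, then epoch
  flat <- as.vector(aperm(es@epochs, c(3L, 2L, 1L)))
  con <- file(binPath, "wb")
  writeBin(flat, con, size = 4L, endian = "little")
  close(con)
  manifest <- list(
    format = "multits-epoch-store",
    version = 1L,
    dtype = "float32",
    byteOrder = "little",
    layout = "epoch-major; sample fastest, then channel, then epoch",
    nEpochs = d[1L], nChannels = d[2L], windowSamples = d[3L],
    fs = es@fs, windowS = es@windowS,
    channelNames = es@channelNames,
    labelLevels = levels(es@labels),
    labels = as.integer(es@labels),
    subjectIds = es@subjectIds,
    nBytes = file.info(binPath)$size,
    md5 = unname(tools::md5sum(binPath))
  )
  manifestPath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifestPath)
}

#' Load an epoch store written by [saveEpochStore()]
#'
#' Verifies the byte length and checksum recorded in the manifest before
#' reconstructing the epoch array; any mismatch is an integrity error.
#'
#' @param dir directory holding `manifest.json` and `epochs.bin`.
#' @return an [EEGEpochSet-class].
#' @export
loadEpochStore <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  binPath <- file.path(dir, "epochs.bin")
  if (!file.exists(manifestPath) || !file.exists(binPath))
    stop("not an epoch store: missing manifest.json or epochs.bin in ", dir)
  m <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  if (!identical(m$format, "multits-epoch-store"))
    stop("unrecognised epoch-store manifest format")
  need <- as.numeric(m$nEpochs) * m$nChannels * m$windowSamples
  sz <- file.info(binPath)$size
  if (!isTRUE(sz == 4 * need))
    stop("epoch store integrity error: epochs.bin has ", sz,
         " bytes, manifest implies ", 4 * need)
  if (!is.null(m$md5) && !identical(unname(tools::md5sum(binPath)), m$md5))
    stop("epoch store integrity error: checksum mismatch")
  con <- file(binPath, "rb")
  flat <- readBin(con, "numeric", n = need, size = 4L, endian = "little")
  close(con)
  ep <- aperm(array(flat, dim = c(m$windowSamples, m$nChannels, m$nEpochs)),
              c(3L, 2L, 1L))
  eegEpochSet(ep,
              labels = m$labelLevels[m$labels],
              subjectIds = m$subjectIds,
              fs = m$fs, windowS = m$windowS,
              channelNames = m$channelNames,
              labelLevels = m$labelLevels)
}
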