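#' Welch power spectral density estimate
#'
#' @slot freqs frequency grid, Hz, ascending from 0 to Nyquist.
#' @slot power channels x frequencies density matrix, microvolt^2 / Hz.
#' @slot fs sampling rate, Hz.
#' @slot segmentS segment length used, seconds.
#' @slot overlapFrac fractional overlap between segments.
#' @seealso [welchPsd()]
#' @export
setClass("PsdEstimate",
  representation(freqs = "numeric", power = "matrix", fs = "numeric",
                 segmentS = "numeric", overlapFrac = "numeric")
)

setValidity("PsdEstimate", function(object) {
  if (any(object@power < 0)) return("spectral power must be non-negative")
  if (is.unsorted(object@freqs)) return("freqs must ascend")
  TRUE
})

setMethod("show", "PsdEstimate", function(object) {
  cat(sprintf("PsdEstimate: %d channel(s), %d bins (0-%.4g Hz), Welch segments %g s @ %.0f%% overlap\n",
              nrow(object@power), length(object@freqs), max(object@freqs),
              object@segmentS, 100 * object@overlapFrac))
})

#' Welch PSD of a multi-channel epoch
#'
#' Averaged modified periodograms: the signal is cut into Hann-tapered
#' segments of `segmentS` seconds advancing by
#' `segmentS * (1 - overlapFrac)`, each segment's periodogram is computed
#' with density scaling (integrating the one-sided density over frequency
#' approximates the signal variance), and segments are averaged per
#' channel.
#'
#' @param epoch channels x samples numeric matrix (a vector is treated as
#'   one channel), microvolts.
#' @param fs sampling rate, Hz.
#' @param segmentS segment length, seconds (default 1 s).
#' @param overlapFrac fractional overlap in `[0, 1)` (default 0.5).
#' @param demean subtract each segment's mean before tapering
#'   (default TRUE; suppresses DC leakage).
#' @return a [PsdEstimate-class].
#' @examples
#' x <- sin(2 * pi * 10 * (0:399) / 200)
#' psd <- welchPsd(x, fs = 200)
#' psd@freqs[which.max(psd@power[1, ])]  # 10 Hz
#' @export
welchPsd <- function(epoch, fs, segmentS = 1, overlapFrac = 0.5,
                     demean = TRUE) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1L)
  nseg <- as.integer(round(segmentS * fs))
  if (nseg < 8L) stop("segmentS x fs must be at least 8 samples")
  if (overlapFrac < 0 || overlapFrac >= 1)
    stop("overlapFrac must lie in [0, 1)")
  n <- ncol(epoch)
  if (n < nseg) stop("epoch is shorter than one Welch segment")
  hop <- max(1L, as.integer(round(nseg * (1 - overlapFrac))))
  starts <- seq(1L, n - nseg + 1L, by = hop)

  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / nseg)   # periodic Hann
  u <- sum(w^2)                                          # window power norm
  nfreq <- nseg %/% 2 + 1L
  freqs <- (0:(nfreq - 1)) * fs / nseg

  power <- matrix(0, nrow(epoch), nfreq)
  for (st in starts) {
    seg <- epoch[, st:(st + nseg - 1L), drop = FALSE]
    if (demean) seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2L, w, `*`)
    ft <- t(apply(seg, 1L, stats::fft))
    pxx <- Mod(ft[, seq_len(nfreq), drop = FALSE])^2 / (fs * u)
    # one-sided density: double every bin except DC (and Nyquist when even)
    dbl <- rep(2, nfreq); dbl[1L] <- 1
    if (nseg %% 2L == 0L) dbl[nfreq] <- 1
    power <- power + sweep(pxx, 2L, dbl, `*`)
  }
  power <- power / length(starts)
  new("PsdEstimate", freqs = freqs, power = power, fs = fs,
      segmentS = nseg / fs, overlapFrac = overlapFrac)
}

#' Integrate spectral density over a frequency band
#'
#' Integrates the Welch density over the bins with `lo <= f < hi`
#' (half-open, so adjacent bands never double-count a bin) as a Riemann
#' sum, `sum(power) * df`: every selected bin carries full weight, so a
#' spectral peak contributes the same total whether it sits mid-band or
#' next to a band edge.
#'
#' @param psd a [PsdEstimate-class].
#' @param band numeric `c(lo, hi)` in Hz with `lo < hi <= Nyquist`.
#' @return per-channel band power, microvolt^2.
#' @export
bandPower <- function(psd, band) {
  stopifnot(is(psd, "PsdEstimate"), length(band) == 2L)
  lo <- band[1L]; hi <- band[2L]
  nyq <- psd@fs / 2
  if (!(lo < hi) || hi > nyq + 1e-9)
    stop("band must satisfy lo < hi <= Nyquist")
  sel <- which(psd@freqs >= lo & psd@freqs < hi)
  if (length(sel) == 0L)
    stop("band [", lo, ", ", hi, ") contains no spectral bins")
  df <- psd@freqs[2L] - psd@freqs[1L]
  rowSums(psd@power[, sel, drop = FALSE]) * df
}

#' Band-power feature matrix for an epoch set
#'
#' The classical PSD feature set: for every epoch and channel, the Welch
#' power integrated over theta, alpha, beta and gamma, flattened
#' channel-major into an epochs x (channels * bands) matrix with
#' `<channel>_<band>` column names.  When the Nyquist frequency does not
#' reach the gamma band, the gamma columns are dropped with a message.
#'
#' @param es an [EEGEpochSet-class].
#' @param bands band-edge matrix (default [eegBands()] capped at Nyquist).
#' @param segmentS,overlapFrac Welch parameters, see [welchPsd()].
#' @param log10Power return log10(power + eps) instead of raw power.
#' @return numeric matrix of band powers with attribute `bands`.
#' @export
extractBandFeatures <- function(es, bands = eegBands(samplingRate(es)),
                                segmentS = 1, overlapFrac = 0.5,
                                log10Power = FALSE) {
  stopifnot(is(es, "EEGEpochSet"))
  nyq <- es@fs / 2
  keep <- bands[, 1L] < nyq
  if (!all(keep)) {
    message("dropping band(s) above Nyquist: ",
            paste(rownames(bands)[!keep], collapse = ", "))
    bands <- bands[keep, , drop = FALSE]
  }
  bands[, 2L] <- pmin(bands[, 2L], nyq)
  nb <- nrow(bands)
  C <- nChannels(es)
  out <- matrix(0, nEpochs(es), C * nb)
  colnames(out) <- as.vector(t(outer(es@channelNames, rownames(bands),
                                     paste, sep = "_")))
  for (i in seq_len(nEpochs(es))) {
    psd <- welchPsd(es@epochs[i, , , drop = TRUE], fs = es@fs,
                    segmentS = segmentS, overlapFrac = overlapFrac)
    if (C == 1L) psd@power <- matrix(psd@power, nrow = 1L)
    bp <- vapply(seq_len(nb),
                 function(b) bandPower(psd, bands[b, ]), numeric(C))
    out[i, ] <- as.vector(t(bp))       # channel-major: ch1 bands, ch2 bands...
  }
  if (log10Power) out <- log10(out + 1e-12)
  attr(out, "bands") <- bands
  out
}
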