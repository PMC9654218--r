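#' Canonical EEG frequency bands
#'
#' The four bands used throughout: theta 4-7 Hz, alpha 8-12 Hz, beta
#' 13-32 Hz and gamma above 32 Hz.  Band membership is half-open
#' `[lo, hi)` so no spectral bin is counted twice; the open-ended gamma
#' band is capped at 45 Hz by default (the upper edge of the common
#' 4-45 Hz emotion-EEG bandpass), or at the Nyquist frequency if lower.
#'
#' @param fs optional sampling rate; when given, the gamma upper edge is
#'   `min(45, fs/2)`.
#' @return a 4 x 2 matrix with rows theta, alpha, beta, gamma and columns
#'   `lo`, `hi` (Hz).
#' @examples
#' eegBands()
#' @export
eegBands <- function(fs = NULL) {
  b <- rbind(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 32),
             gamma = c(32, 45))
  colnames(b) <- c("lo", "hi")
  if (!is.null(fs)) b["gamma", "hi"] <- min(45, fs / 2)
  b
}

defaultTopography <- function(nChannels) {
  # smooth weights over a left(-1) .. right(+1) electrode axis; alpha and
  # gamma carry opposite hemispheric asymmetry, theta peaks midline
  x <- if (nChannels > 1L) seq(-1, 1, length.out = nChannels) else 0
  topo <- rbind(
    theta = 0.8 + 0.4 * exp(-2 * x^2),
    alpha = 1 + 0.3 * x,
    beta  = rep(1, nChannels),
    gamma = 1 - 0.3 * x
  )
  colnames(topo) <- paste0("Ch", seq_len(nChannels))
  topo
}

#' Configure the synthetic labelled-EEG generator
#'
#' Builds a [SynthConfig-class] describing a simulated emotion-EEG study:
#' band-limited oscillations with class-dependent amplitudes, per-band
#' spatial topographies with hemispheric asymmetry, 1/f background noise,
#' 2 s epochs and per-subject amplitude shifts.  Defaults mirror a
#' SEED-like study: 15 subjects, 62 channels at 200 Hz, three emotion
#' classes (negative / neutral / positive) separated mainly in the alpha
#' and gamma bands.
#'
#' @param nSubjects number of subjects.
#' @param epochsPerClassPerSubject balanced epochs per class per subject.
#' @param fs sampling rate, Hz.
#' @param nChannels electrode count.
#' @param windowS epoch length, seconds.
#' @param classBandAmplitude class x band amplitude matrix (microvolts);
#'   row names name the classes, columns follow `bandEdges`.
#' @param bandEdges 4 x 2 band-edge matrix, Hz (default [eegBands()]).
#' @param topography band x channel non-negative weight matrix.
#' @param noiseExponent spectral slope a of the 1/f^a background.
#' @param noiseScale background RMS, microvolts.
#' @param subjectJitter relative sd of per-subject band-amplitude
#'   multipliers (distribution shift across subjects).
#' @param seed integer seed; generation is a pure function of the config.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(nSubjects = 15L,
                        epochsPerClassPerSubject = 60L,
                        fs = 200,
                        nChannels = 62L,
                        windowS = 2,
                        classBandAmplitude = NULL,
                        bandEdges = eegBands(fs),
                        topography = NULL,
                        noiseExponent = 1,
                        noiseScale = 10,
                        subjectJitter = 0.2,
                        seed = 1L) {
  if (is.null(classBandAmplitude)) {
    classBandAmplitude <- rbind(
      negative = c(theta = 6, alpha = 10, beta = 5, gamma = 4),
      neutral  = c(theta = 6, alpha = 8,  beta = 5, gamma = 5),
      positive = c(theta = 6, alpha = 6,  beta = 5, gamma = 6)
    )
  }
  if (is.null(topography))
    topography <- defaultTopography(nChannels)[seq_len(nrow(bandEdges)), ,
                                               drop = FALSE]
  new("SynthConfig",
      nSubjects = as.integer(nSubjects),
      epochsPerClassPerSubject = as.integer(epochsPerClassPerSubject),
      fs = as.numeric(fs), nChannels = as.integer(nChannels),
      windowS = as.numeric(windowS),
      classBandAmplitude = as.matrix(classBandAmplitude),
      bandEdges = as.matrix(bandEdges),
      topography = as.matrix(topography),
      noiseExponent = as.numeric(noiseExponent),
      noiseScale = as.numeric(noiseScale),
      subjectJitter = as.numeric(subjectJitter),
      seed = as.integer(seed))
}

# one epoch of 1/f^a noise, channels x samples, unit RMS per channel
pinkNoise <- function(nChannels, n, fs, exponent) {
  k <- 0:(n - 1)
  fsym <- pmin(k, n - k) * fs / n   # symmetric so the filtered fft stays Hermitian
  shape <- ifelse(fsym == 0, 0, fsym^(-exponent / 2))
  out <- matrix(0, nChannels, n)
  for (c in seq_len(nChannels)) {
    w <- stats::rnorm(n)
    x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
    out[c, ] <- x / stats::sd(x)
  }
  out
}

#' Generate a synthetic labelled EEG epoch set
#'
#' Each epoch is a sum over bands of
#' `amplitude(class, band) * subjectMultiplier(subject, band) *
#' topography(band, channel) * sin(2 pi f t + phase)` with the oscillation
#' frequency drawn uniformly inside the band and the phase uniform on
#' `[0, 2 pi)`, plus independent per-channel 1/f background noise.  Labels
#' are balanced per subject.  Output is bit-identical across calls with
#' the same configuration.
#'
#' @param cfg a [SynthConfig-class].
#' @return an [EEGEpochSet-class] with
#'   `nSubjects * nClasses * epochsPerClassPerSubject` epochs, labels from
#'   the row names of `classBandAmplitude` and subject ids `S1..Sn`.
#' @examples
#' cfg <- synthConfig(nSubjects = 2L, epochsPerClassPerSubject = 3L,
#'                    nChannels = 4L, fs = 128)
#' es <- generateSyntheticDataset(cfg)
#' table(epochLabels(es), subjectIds(es))
#' @export
generateSyntheticDataset <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  fs <- cfg@fs
  n <- as.integer(round(cfg@windowS * fs))
  tgrid <- (0:(n - 1)) / fs
  classes <- rownames(cfg@classBandAmplitude)
  if (is.null(classes))
    classes <- paste0("class", seq_len(nrow(cfg@classBandAmplitude)))
  nBands <- nrow(cfg@bandEdges)
  nTotal <- cfg@nSubjects * length(classes) * cfg@epochsPerClassPerSubject

  set.seed(cfg@seed)
  subjMult <- matrix(pmax(0.1, 1 + cfg@subjectJitter *
                            stats::rnorm(cfg@nSubjects * nBands)),
                     cfg@nSubjects, nBands)

  ep <- array(0, dim = c(nTotal, cfg@nChannels, n))
  labels <- character(nTotal)
  subjects <- character(nTotal)
  i <- 0L
  for (s in seq_len(cfg@nSubjects)) {
    for (cl in seq_along(classes)) {
      for (k in seq_len(cfg@epochsPerClassPerSubject)) {
        i <- i + 1L
        x <- if (cfg@noiseScale > 0)
          cfg@noiseScale * pinkNoise(cfg@nChannels, n, fs, cfg@noiseExponent)
        else matrix(0, cfg@nChannels, n)
        for (b in seq_len(nBands)) {
          amp <- cfg@classBandAmplitude[cl, b] * subjMult[s, b]
          if (amp <= 0) next
          lo <- cfg@bandEdges[b, 1L]
          hi <- min(cfg@bandEdges[b, 2L], 0.45 * fs)
          f <- stats::runif(1, lo, hi)
          phase <- stats::runif(1, 0, 2 * pi)
          wave <- sin(2 * pi * f * tgrid + phase)
          x <- x + (amp * cfg@topography[b, ]) %o% wave
        }
        ep[i, , ] <- x
        labels[i] <- classes[cl]
        subjects[i] <- paste0("S", s)
      }
    }
  }
  eegEpochSet(ep, labels = labels, subjectIds = subjects, fs = fs,
              windowS = n / fs,
              channelNames = paste0("Ch", seq_len(cfg@nChannels)),
              labelLevels = classes)
}
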