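# Shared fixtures, built in code at test time.

# deterministic multi-sine recording: one frequency per channel
sineRecording <- function(freqs = c(10, 25), fs = 200, seconds = 10,
                          amp = 50, subjectId = "S1") {
  t <- (0:(fs * seconds - 1)) / fs
  sig <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t),
                  numeric(length(t))))
  eegRecording(sig, fs = fs, subjectId = subjectId)
}

# two-class alpha-amplitude contrast generator config
alphaContrastConfig <- function(nSubjects = 2L, epochsPerClass = 25L,
                                fs = 100, nChannels = 4L, noise = 6,
                                ampHi = 9, ampLo = 4, seed = 11L) {
  amp <- rbind(neg = c(theta = 3, alpha = ampHi, beta = 3, gamma = 2),
               pos = c(theta = 3, alpha = ampLo, beta = 3, gamma = 2))
  synthConfig(nSubjects = nSubjects,
              epochsPerClassPerSubject = epochsPerClass, fs = fs,
              nChannels = nChannels, classBandAmplitude = amp,
              noiseScale = noise, seed = seed)
}

# class signal split between a slow (5 Hz) and a fast (35 Hz) component
dualBandConfig <- function(nSubjects = 2L, epochsPerClass = 30L,
                           fs = 100, nChannels = 4L, noise = 6,
                           seed = 12L) {
  amp <- rbind(neg = c(theta = 8, alpha = 0, beta = 0, gamma = 7),
               pos = c(theta = 4, alpha = 0, beta = 0, gamma = 3.5))
  # pin the two components at ~5 Hz and ~35 Hz via narrow band edges
  bands <- rbind(theta = c(4.5, 5.5), alpha = c(8, 12), beta = c(13, 32),
                 gamma = c(34, 36))
  colnames(bands) <- c("lo", "hi")
  synthConfig(nSubjects = nSubjects,
              epochsPerClassPerSubject = epochsPerClass, fs = fs,
              nChannels = nChannels, classBandAmplitude = amp,
              bandEdges = bands, noiseScale = noise, seed = seed)
}

# reduced MultiT-S instantiation used for the training properties
smallMultitsSpec <- function(fs = 100, nChannels = 4L, seed = 1L,
                             useSE = TRUE,
                             branchKernelsMs = c(25, 50, 100, 200)) {
  multitsSpec(fs = fs, nChannels = nChannels, filtersPerBranch = 4L,
              spatialFilters = 8L, seRatio = 4L, useSE = useSE,
              branchKernelsMs = branchKernelsMs, seed = seed)
}

# labels/subjects-only epoch set (1-sample dummy signal) for CV planning
planningEpochSet <- function(labels, subjects, fs = 10, windowS = 0.1) {
  n <- length(labels)
  eegEpochSet(array(0, dim = c(n, 1L, round(fs * windowS))),
              labels = labels, subjectIds = subjects, fs = fs,
              windowS = windowS)
}

# single held-out train/test evaluation of a ConvNet spec on an epoch set;
# returns test accuracy (fold 1 of a seeded subject-stratified 5-fold plan)
heldOutAccuracy <- function(spec, es, epochs = 30L, seed = 1L,
                            batch = 100L) {
  plan <- planSubjectDependent(es, k = 5L, seed = seed)
  f <- plan@folds[[1L]]
  x <- multits:::epochsToTensor(epochArray(es))
  st <- multits:::channelStats(x[, , , f$train, drop = FALSE])
  xtr <- multits:::applyChannelStats(x[, , , f$train, drop = FALSE], st)
  xva <- multits:::applyChannelStats(x[, , , f$val, drop = FALSE], st)
  xte <- multits:::applyChannelStats(x[, , , f$test, drop = FALSE], st)
  y <- as.integer(epochLabels(es))
  spec@seed <- as.integer(seed)
  net <- buildModel(spec)
  tr <- trainConvNet(net, xtr, y[f$train], xva, y[f$val],
                     trainConfig(epochs = epochs, batch = batch,
                                 seed = seed))
  mean(predictConvNet(tr$net, xte) == y[f$test])
}
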