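test_that("epoching tiles the recording and discards the trailing partial window", {
  rec <- sineRecording(c(10, 25), fs = 200, seconds = 10)
  es <- epochRecording(rec, windowS = 2, label = "neutral")
  expect_equal(nEpochs(es), 5L)
  expect_equal(nSamples(es), 400L)          # 2 s at 200 Hz
  expect_equal(nChannels(es), 2L)
  expect_true(all(epochLabels(es) == "neutral"))
  expect_true(all(subjectIds(es) == "S1"))

  # exactly one window when the recording equals the window
  rec2 <- sineRecording(10, fs = 200, seconds = 2)
  expect_equal(nEpochs(epochRecording(rec2, windowS = 2)), 1L)

  # overlapping stride: floor((5 - 2)/1) + 1 = 4
  rec5 <- sineRecording(10, fs = 200, seconds = 5)
  expect_equal(nEpochs(epochRecording(rec5, windowS = 2, strideS = 1)), 4L)

  expect_error(epochRecording(sineRecording(10, fs = 200, seconds = 1),
                              windowS = 2), "shorter than one window")
})

test_that("non-overlapping epochs concatenate back to the covered prefix", {
  rec <- sineRecording(c(7, 19, 31), fs = 128, seconds = 5.3)
  es <- epochRecording(rec, windowS = 1)
  n <- nEpochs(es); w <- nSamples(es)
  expect_lte(n * w, nSamples(rec))
  rebuilt <- do.call(cbind, lapply(seq_len(n), function(i)
    matrix(epochArray(es)[i, , ], nrow = nChannels(es))))
  expect_equal(rebuilt, rec@signal[, seq_len(n * w)], ignore_attr = TRUE)
})

test_that("ratings binarise at 5 and reject out-of-range values", {
  expect_equal(as.character(binarizeRating(c(3, 5, 4.5, 1, 9))),
               c("negative", "positive", "negative", "negative",
                 "positive"))
  expect_error(binarizeRating(0.5), "1, 9")
  expect_error(binarizeRating(9.1), "1, 9")
})

test_that("dropping neutral keeps order and two-thirds of a balanced 3-class set", {
  labs <- rep(c("positive", "negative", "neutral"), 30)
  es <- planningEpochSet(labs, rep("S1", 90))
  out <- dropNeutral(es)
  expect_equal(nEpochs(out), 60L)
  expect_equal(as.character(epochLabels(out)),
               labs[labs != "neutral"])
  expect_false("neutral" %in% levels(epochLabels(out)))

  allNeu <- dropNeutral(planningEpochSet(rep("neutral", 4), rep("S1", 4)))
  expect_equal(nEpochs(allNeu), 0L)
})

test_that("EDF round trip preserves geometry and stays within quantisation error", {
  rec <- sineRecording(c(10, 25), fs = 200, seconds = 10, amp = 50)
  path <- tempfile(fileext = ".edf")
  writeEDF(rec, path, physicalRange = 100)
  back <- readEDF(path)
  expect_equal(nChannels(back), 2L)
  expect_equal(nSamples(back), 2000L)
  expect_equal(samplingRate(back), 200)
  # 16-bit quantisation over [-100, 100] uV
  qstep <- 200 / (32767 - (-32768))
  expect_lte(max(abs(back@signal - rec@signal)), qstep)

  bad <- tempfile(fileext = ".edf")
  writeBin(charToRaw("X       not an edf file"), bad)
  expect_error(readEDF(bad), "not an EDF")
})

test_that("the epoch store round-trips losslessly at float32 and detects tampering", {
  cfg <- alphaContrastConfig(nSubjects = 2L, epochsPerClass = 3L)
  es <- generateSyntheticDataset(cfg)
  dir <- tempfile("store")
  saveEpochStore(es, dir)
  back <- loadEpochStore(dir)
  expect_equal(dim(epochArray(back)), dim(epochArray(es)))
  expect_equal(as.character(epochLabels(back)),
               as.character(epochLabels(es)))
  expect_equal(levels(epochLabels(back)), levels(epochLabels(es)))
  expect_equal(subjectIds(back), subjectIds(es))
  expect_equal(samplingRate(back), samplingRate(es))
  # float32 storage: agreement to single precision
  expect_lt(max(abs(epochArray(back) - epochArray(es))),
            1e-4 * max(abs(epochArray(es))))
  # re-reading yields the identical checksum recorded in the manifest
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  expect_identical(unname(tools::md5sum(file.path(dir, "epochs.bin"))),
                   m$md5)

  # tampering with the blob length is an integrity error
  con <- file(file.path(dir, "epochs.bin"), "ab")
  writeBin(0L, con, size = 4L); close(con)
  expect_error(loadEpochStore(dir), "integrity")
})

test_that("the generator is a pure function of its configuration", {
  cfg <- alphaContrastConfig(nSubjects = 2L, epochsPerClass = 4L)
  a <- generateSyntheticDataset(cfg)
  b <- generateSyntheticDataset(cfg)
  expect_identical(epochArray(a), epochArray(b))
  expect_identical(epochLabels(a), epochLabels(b))
  # balanced labels per subject
  tab <- table(epochLabels(a), subjectIds(a))
  expect_true(all(tab == 4L))
})

test_that("class-dependent alpha amplitudes shape band power as amplitude squared", {
  # identical rows -> no class signal in alpha power (< 5% relative)
  ampNull <- rbind(neg = c(3, 6, 3, 2), pos = c(3, 6, 3, 2))
  cfgNull <- synthConfig(nSubjects = 2L, epochsPerClassPerSubject = 120L,
                         fs = 100, nChannels = 2L,
                         classBandAmplitude = ampNull, noiseScale = 2,
                         subjectJitter = 0, seed = 4L)
  esN <- generateSyntheticDataset(cfgNull)
  Xn <- extractBandFeatures(esN)
  aCols <- grep("alpha", colnames(Xn))
  mNeg <- mean(Xn[epochLabels(esN) == "neg", aCols])
  mPos <- mean(Xn[epochLabels(esN) == "pos", aCols])
  expect_lt(abs(mNeg - mPos) / mNeg, 0.05)

  # amplitude ratio 2 -> alpha power ratio ~= 4 within 15% at 200+ epochs/class
  amp2 <- rbind(c0 = c(0, 4, 0, 0), c1 = c(0, 8, 0, 0))
  cfg2 <- synthConfig(nSubjects = 2L, epochsPerClassPerSubject = 100L,
                      fs = 100, nChannels = 2L, classBandAmplitude = amp2,
                      noiseScale = 0.5, subjectJitter = 0, seed = 5L)
  es2 <- generateSyntheticDataset(cfg2)
  X2 <- extractBandFeatures(es2)
  aCols <- grep("alpha", colnames(X2))
  ratio <- mean(X2[epochLabels(es2) == "c1", aCols]) /
    mean(X2[epochLabels(es2) == "c0", aCols])
  expect_lt(abs(ratio - 4) / 4, 0.15)
})

test_that("a single-band noiseless configuration concentrates its spectrum in band", {
  amp <- rbind(only = c(0, 6, 0, 0))      # alpha only, no noise
  cfg <- synthConfig(nSubjects = 1L, epochsPerClassPerSubject = 10L,
                     fs = 100, nChannels = 2L, classBandAmplitude = amp,
                     noiseScale = 0, subjectJitter = 0, seed = 6L)
  es <- generateSyntheticDataset(cfg)
  # oracle: direct periodogram (single full-length segment, no overlap)
  for (i in seq_len(nEpochs(es))) {
    psd <- welchPsd(epochArray(es)[i, , ], fs = 100,
                    segmentS = nSamples(es) / 100, overlapFrac = 0)
    inBand <- psd@freqs >= 7.5 & psd@freqs < 12.5
    frac <- sum(psd@power[, inBand]) / sum(psd@power)
    expect_gt(frac, 0.95)
  }
})

test_that("the configured class band-power log-ratio is recovered from generated data", {
  # 2x amplitude -> log-ratio log(4); n = 500 epochs/class
  amp <- rbind(c0 = c(0, 4, 0, 0), c1 = c(0, 8, 0, 0))
  cfg <- synthConfig(nSubjects = 1L, epochsPerClassPerSubject = 500L,
                     fs = 100, nChannels = 1L, classBandAmplitude = amp,
                     noiseScale = 1, subjectJitter = 0, seed = 7L)
  es <- generateSyntheticDataset(cfg)
  X <- log(extractBandFeatures(es)[, 2L])   # alpha column
  g <- epochLabels(es)
  est <- mean(X[g == "c1"]) - mean(X[g == "c0"])
  se <- sqrt(stats::var(X[g == "c1"]) / sum(g == "c1") +
               stats::var(X[g == "c0"]) / sum(g == "c0"))
  expect_lt(abs(est - log(4)), 3 * se)
})

test_that("band centres above Nyquist are a configuration error", {
  expect_error(synthConfig(fs = 60, bandEdges = eegBands()),
               "Nyquist")
})
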