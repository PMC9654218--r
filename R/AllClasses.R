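#' @import methods
NULL

#' Continuous multi-channel EEG recording
#'
#' Holds a continuous EEG recording as a channels-by-samples matrix in
#' microvolts, together with its sampling rate, ordered channel names and a
#' subject identifier.  This is the raw "2-D time series" whose axes are time
#' and electrode channels; all downstream epoching and modelling starts here.
#'
#' @slot signal numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector, one name per channel (row).
#' @slot subjectId subject identifier.
#'
#' @seealso [eegRecording()], [readEDF()], [epochRecording()]
#' @export
setClass("EEGRecording",
  representation(
    signal = "matrix",
    fs = "numeric",
    channelNames = "character",
    subjectId = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@signal) < 1L)
    msg <- c(msg, "recording must have at least one channel")
  if (nrow(object@signal) != length(object@channelNames))
    msg <- c(msg, "channel count must equal length(channelNames)")
  if (anyNA(object@signal) || any(!is.finite(object@signal)))
    msg <- c(msg, "signal contains non-finite samples")
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param channelNames channel names; defaults to `Ch1..Chn`.
#' @param subjectId subject identifier.
#' @return an [EEGRecording-class] object.
#' @examples
#' rec <- eegRecording(matrix(rnorm(400), 2), fs = 100)
#' nChannels(rec)
#' @export
eegRecording <- function(signal, fs,
                         channelNames = paste0("Ch", seq_len(nrow(signal))),
                         subjectId = "S1") {
  new("EEGRecording", signal = signal, fs = as.numeric(fs),
      channelNames = as.character(channelNames),
      subjectId = as.character(subjectId))
}

#' Set of fixed-length labelled EEG epochs
#'
#' Fixed-duration windows cut from one or more recordings, stored as an
#' epochs x channels x samples array with a discrete emotion label and a
#' subject identifier per epoch.  A 2 s window is the canonical choice
#' (400 samples at 200 Hz).
#'
#' @slot epochs numeric array, n x channels x window samples, microvolts.
#' @slot labels factor of per-epoch class labels.
#' @slot subjectIds character vector of per-epoch subject ids.
#' @slot fs sampling rate, Hz.
#' @slot windowS window length in seconds.
#' @slot channelNames channel names.
#'
#' @seealso [epochRecording()], [generateSyntheticDataset()],
#'   [saveEpochStore()]
#' @export
setClass("EEGEpochSet",
  representation(
    epochs = "array",
    labels = "factor",
    subjectIds = "character",
    fs = "numeric",
    windowS = "numeric",
    channelNames = "character"
  )
)

setValidity("EEGEpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L)
    msg <- c(msg, "epochs must be a 3-D array (epoch x channel x sample)")
  else {
    if (d[1L] != length(object@labels))
      msg <- c(msg, "one label per epoch required")
    if (d[1L] != length(object@subjectIds))
      msg <- c(msg, "one subject id per epoch required")
    if (d[2L] != length(object@channelNames))
      msg <- c(msg, "channel count must equal length(channelNames)")
    if (d[3L] != round(object@windowS * object@fs))
      msg <- c(msg, "window samples must equal round(windowS * fs)")
  }
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyNA(object@labels))
    msg <- c(msg, "labels must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGEpochSet
#'
#' @param epochs n x channels x samples array (microvolts).
#' @param labels per-epoch class labels (coerced to factor).
#' @param subjectIds per-epoch subject identifiers.
#' @param fs sampling rate, Hz.
#' @param windowS window length, seconds.
#' @param channelNames channel names.
#' @param labelLevels optional explicit label level set.
#' @return an [EEGEpochSet-class] object.
#' @export
eegEpochSet <- function(epochs, labels, subjectIds, fs, windowS,
                        channelNames = paste0("Ch", seq_len(dim(epochs)[2L])),
                        labelLevels = NULL) {
  labels <- if (is.null(labelLevels)) factor(labels)
            else factor(labels, levels = labelLevels)
  new("EEGEpochSet", epochs = epochs, labels = labels,
      subjectIds = as.character(subjectIds), fs = as.numeric(fs),
      windowS = as.numeric(windowS),
      channelNames = as.character(channelNames))
}

#' Configuration of the synthetic labelled-EEG generator
#'
#' Describes the simulated study: subjects, balanced epochs per class,
#' per-class band-limited oscillation amplitudes over the four canonical
#' EEG bands (theta 4-7 Hz, alpha 8-12 Hz, beta 13-32 Hz, gamma >32 Hz),
#' per-band spatial topographies across channels, 1/f background noise and
#' per-subject amplitude jitter.  Generation is a pure function of the
#' configuration (including its seed).
#'
#' @slot nSubjects number of simulated subjects.
#' @slot epochsPerClassPerSubject balanced epoch count per class and subject.
#' @slot fs sampling rate, Hz.
#' @slot nChannels channel count.
#' @slot windowS epoch length, seconds.
#' @slot classBandAmplitude class x band matrix of oscillation amplitudes
#'   (microvolts); row names are the class labels.
#' @slot bandEdges 4 x 2 matrix of band edges in Hz (rows theta, alpha,
#'   beta, gamma).
#' @slot topography band x channel matrix of non-negative spatial weights.
#' @slot noiseExponent spectral slope of the 1/f^a background noise.
#' @slot noiseScale background noise RMS amplitude, microvolts.
#' @slot subjectJitter relative sd of per-subject amplitude multipliers.
#' @slot seed integer RNG seed.
#' @seealso [synthConfig()], [generateSyntheticDataset()]
#' @export
setClass("SynthConfig",
  representation(
    nSubjects = "integer",
    epochsPerClassPerSubject = "integer",
    fs = "numeric",
    nChannels = "integer",
    windowS = "numeric",
    classBandAmplitude = "matrix",
    bandEdges = "matrix",
    topography = "matrix",
    noiseExponent = "numeric",
    noiseScale = "numeric",
    subjectJitter = "numeric",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (any(object@classBandAmplitude < 0))
    msg <- c(msg, "oscillation amplitudes must be >= 0")
  if (ncol(object@classBandAmplitude) != nrow(object@bandEdges))
    msg <- c(msg, "one amplitude column per band required")
  nyq <- object@fs / 2
  lo <- object@bandEdges[, 1L]; hi <- object@bandEdges[, 2L]
  if (any(lo >= hi))
    msg <- c(msg, "band edges must satisfy lo < hi")
  if (any(hi[-length(hi)] > lo[-1L]))
    msg <- c(msg, "bands must not overlap")
  if (any((lo + hi) / 2 >= nyq))
    msg <- c(msg, "band centres must lie below the Nyquist frequency")
  if (nrow(object@topography) != nrow(object@bandEdges) ||
      ncol(object@topography) != object@nChannels)
    msg <- c(msg, "topography must be band x channel")
  if (any(object@topography < 0))
    msg <- c(msg, "topography weights must be >= 0")
  if (object@nSubjects < 1L || object@epochsPerClassPerSubject < 1L)
    msg <- c(msg, "at least one subject and one epoch per class required")
  if (length(msg)) msg else TRUE
})

#' Declarative ConvNet architecture description
#'
#' A ModelSpec fully determines an architecture: the family (MultiT-S,
#' Deep ConvNet, Shallow ConvNet or EEGNet), the input geometry (window
#' length, sampling rate, channel count), the branch kernel durations in
#' milliseconds (kernels are stored as durations so the same receptive
#' time scales carry across sampling rates), filter counts, the
#' squeeze-and-excitation ratio, pooling, and the classifier head.  Models
#' are built from the spec ([buildModel()]) and trainable parameters are
#' counted from it analytically ([countParamsClosedForm()]).
#'
#' @slot family one of `"multits"`, `"deep"`, `"shallow"`, `"eegnet"`.
#' @slot fs sampling rate, Hz.
#' @slot windowS input window, seconds.
#' @slot nChannels electrode count E.
#' @slot nClasses 2 or 3.
#' @slot branchKernelsMs multi-kernel branch durations, ms (empty when the
#'   family is single-kernel and not reformed).
#' @slot filtersPerBranch temporal filters per branch.
#' @slot featureMultiplier depthwise spatial filters per temporal map.
#' @slot spatialFilters pointwise output width Fsp.
#' @slot seRatio squeeze-and-excitation bottleneck ratio r.
#' @slot useSE logical, include the SE blocks (MultiT-S only).
#' @slot batchNorm logical, include batch normalisation stages.
#' @slot temporalKernelMs single-kernel temporal duration, ms.
#' @slot sepKernelMs separable temporal kernel duration, ms (EEGNet).
#' @slot blockFilters filter counts of the deep family's conv blocks.
#' @slot poolSpec named list of pooling lengths/strides per stage.
#' @slot dropout dropout rate (EEGNet family).
#' @slot reformed logical, TRUE after [multikernelify()].
#' @slot seed integer seed for weight initialisation.
#' @export
setClass("ModelSpec",
  representation(
    family = "character",
    fs = "numeric",
    windowS = "numeric",
    nChannels = "integer",
    nClasses = "integer",
    branchKernelsMs = "numeric",
    filtersPerBranch = "integer",
    featureMultiplier = "integer",
    spatialFilters = "integer",
    seRatio = "integer",
    useSE = "logical",
    batchNorm = "logical",
    temporalKernelMs = "numeric",
    sepKernelMs = "numeric",
    blockFilters = "integer",
    poolSpec = "list",
    dropout = "numeric",
    reformed = "logical",
    seed = "integer"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@family %in% c("multits", "deep", "shallow", "eegnet"))
    msg <- c(msg, "unknown model family")
  if (!object@nClasses %in% c(2L, 3L))
    msg <- c(msg, "nClasses must be 2 or 3")
  if (object@fs <= 0 || object@windowS <= 0)
    msg <- c(msg, "fs and windowS must be positive")
  if (length(object@branchKernelsMs) &&
      any(msToSamples(object@branchKernelsMs, object@fs) < 1L))
    msg <- c(msg, "every branch kernel must span at least one sample")
  if (object@seRatio < 1L)
    msg <- c(msg, "seRatio must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Cross-validation plan
#'
#' A list of folds, each holding pairwise-disjoint train / validation /
#' test index sets, together with the policy that produced them.  Test
#' sets partition the epochs (subject-dependent k-fold) or the subjects
#' (leave-one-subject-out).
#'
#' @slot scheme `"subject_dependent_kfold"` or `"loso"`.
#' @slot folds list; each element has `train`, `val`, `test` integer
#'   vectors and (for LOSO) the held-out `subject`.
#' @slot seed integer seed used for the shuffling.
#' @seealso [planSubjectDependent()], [planLOSO()]
#' @export
setClass("CVPlan",
  representation(scheme = "character", folds = "list", seed = "integer")
)

setValidity("CVPlan", function(object) {
  for (f in object@folds) {
    if (length(intersect(f$train, f$val)) || length(intersect(f$train, f$test)) ||
        length(intersect(f$val, f$test)))
      return("train/val/test sets must be pairwise disjoint within a fold")
  }
  TRUE
})

#' Result of a cross-validated classification experiment
#'
#' @slot model short description of the evaluated model.
#' @slot scheme cross-validation scheme used.
#' @slot perFoldAccuracy test accuracy per fold (fractions).
#' @slot perSubjectAccuracy named test accuracy per subject (fractions).
#' @slot mean mean of the per-subject accuracies.
#' @slot sd standard deviation of the per-subject accuracies.
#' @slot ci95 two-sided 95% Student-t interval over subject means.
#' @slot chanceLevel majority-class rate of the full label vector.
#' @slot history per-fold training history (loss / validation accuracy).
#' @export
setClass("EvalResult",
  representation(
    model = "character",
    scheme = "character",
    perFoldAccuracy = "numeric",
    perSubjectAccuracy = "numeric",
    mean = "numeric",
    sd = "numeric",
    ci95 = "numeric",
    chanceLevel = "numeric",
    history = "list"
  )
)

setValidity("EvalResult", function(object) {
  acc <- c(object@perFoldAccuracy, object@perSubjectAccuracy)
  acc <- acc[!is.na(acc)]                      # skipped folds are NA
  if (length(acc) && (any(acc < 0) || any(acc > 1)))
    return("accuracies must lie in [0, 1]")
  subj <- object@perSubjectAccuracy[!is.na(object@perSubjectAccuracy)]
  if (length(subj) &&
      (object@mean < min(subj) - 1e-12 || object@mean > max(subj) + 1e-12))
    return("mean must lie within [min, max] of the per-subject accuracies")
  TRUE
})

#' Model-comparison statistics report
#'
#' One-way ANOVA over per-model accuracy vectors, Dunnett's many-to-one
#' post hoc comparison of every model against a control, and optional
#' paired t-tests, with significance flags at 0.05 and 0.01.
#'
#' @slot anova list with `F`, `p`, `dfBetween`, `dfWithin`.
#' @slot dunnett data.frame of per-comparison mean difference, t statistic
#'   and adjusted p value.
#' @slot pairedT data.frame of paired t-test results (possibly empty).
#' @slot control name of the control group.
#' @export
setClass("ComparisonReport",
  representation(
    anova = "list",
    dunnett = "data.frame",
    pairedT = "data.frame",
    control = "character"
  )
)

setValidity("ComparisonReport", function(object) {
  p <- c(object@anova$p, object@dunnett$p.adjusted, object@pairedT$p)
  p <- p[!is.na(p)]
  if (length(p) && (any(p < 0) || any(p > 1)))
    return("p values must lie in [0, 1]")
  TRUE
})
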