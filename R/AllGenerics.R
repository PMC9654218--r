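#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family for the EEG containers: sampling rate, channel
#' names and counts, epoch counts, labels and subject ids.
#'
#' @param object an [EEGRecording-class] or [EEGEpochSet-class].
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("epochArray", function(object) standardGeneric("epochArray"))

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "EEGEpochSet", function(object) object@fs)
#' @rdname accessors
setMethod("channelNames", "EEGRecording", function(object) object@channelNames)
#' @rdname accessors
setMethod("channelNames", "EEGEpochSet", function(object) object@channelNames)
#' @rdname accessors
setMethod("nChannels", "EEGRecording", function(object) nrow(object@signal))
#' @rdname accessors
setMethod("nChannels", "EEGEpochSet", function(object) dim(object@epochs)[2L])
#' @rdname accessors
setMethod("nSamples", "EEGRecording", function(object) ncol(object@signal))
#' @rdname accessors
setMethod("nSamples", "EEGEpochSet", function(object) dim(object@epochs)[3L])
#' @rdname accessors
setMethod("subjectIds", "EEGRecording", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectIds", "EEGEpochSet", function(object) object@subjectIds)
#' @rdname accessors
setMethod("epochLabels", "EEGEpochSet", function(object) object@labels)
#' @rdname accessors
setMethod("nEpochs", "EEGEpochSet", function(object) dim(object@epochs)[1L])
#' @rdname accessors
setMethod("epochArray", "EEGEpochSet", function(object) object@epochs)

#' Subset an epoch set
#'
#' `es[i]` keeps epochs `i` (labels, subject ids and data stay aligned;
#' unused label levels are preserved so that class sets remain declared).
#'
#' @param x an [EEGEpochSet-class].
#' @param i epoch indices (integer or logical).
#' @param j,...,drop ignored.
#' @return an [EEGEpochSet-class].
#' @export
setMethod("[", "EEGEpochSet", function(x, i, j, ..., drop = FALSE) {
  new("EEGEpochSet",
      epochs = x@epochs[i, , , drop = FALSE],
      labels = x@labels[i],
      subjectIds = x@subjectIds[i],
      fs = x@fs, windowS = x@windowS, channelNames = x@channelNames)
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channel(s) x %d samples @ %g Hz (%.2f s), subject %s\n",
              nChannels(object), nSamples(object), object@fs,
              nSamples(object) / object@fs, object@subjectId))
})

setMethod("show", "EEGEpochSet", function(object) {
  tab <- table(object@labels)
  cat(sprintf("EEGEpochSet: %d epoch(s) x %d channel(s) x %d samples @ %g Hz (window %g s)\n",
              nEpochs(object), nChannels(object), nSamples(object),
              object@fs, object@windowS))
  cat("  labels:  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  subjects:", length(unique(object@subjectIds)), "\n")
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf("SynthConfig: %d subject(s), %d epochs/class/subject, %d classes, %d channel(s) @ %g Hz\n",
              object@nSubjects, object@epochsPerClassPerSubject,
              nrow(object@classBandAmplitude), object@nChannels, object@fs))
  cat(sprintf("  noise: 1/f^%.2g, %.3g uV RMS; subject jitter %.2g; seed %d\n",
              object@noiseExponent, object@noiseScale, object@subjectJitter,
              object@seed))
})

setMethod("show", "ModelSpec", function(object) {
  nm <- c(multits = "MultiT-S ConvNet", deep = "Deep ConvNet",
          shallow = "Shallow ConvNet", eegnet = "EEGNet")[object@family]
  if (isTRUE(object@reformed)) nm <- paste0(nm, " (+ multi-kernel)")
  cat(sprintf("ModelSpec: %s, input %d x %d @ %g Hz, %d classes\n",
              nm, round(object@windowS * object@fs), object@nChannels,
              object@fs, object@nClasses))
  if (length(object@branchKernelsMs))
    cat(sprintf("  branches: %d x {%s} ms -> {%s} samples\n",
                object@filtersPerBranch,
                paste(object@branchKernelsMs, collapse = ", "),
                paste(msToSamples(object@branchKernelsMs, object@fs),
                      collapse = ", ")))
  cat(sprintf("  trainable parameters: %s; minimum frequency covered: %.3g Hz\n",
              format(countParamsClosedForm(object), big.mark = ","),
              minFrequencyCovered(object)))
})

setMethod("show", "CVPlan", function(object) {
  cat(sprintf("CVPlan: %s, %d fold(s), seed %d\n", object@scheme,
              length(object@folds), object@seed))
  sizes <- vapply(object@folds, function(f)
    c(length(f$train), length(f$val), length(f$test)), numeric(3))
  cat(sprintf("  fold sizes (train/val/test): %s\n",
              paste(apply(sizes, 2, paste, collapse = "/"), collapse = ", ")))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: %s [%s]\n", object@model, object@scheme))
  cat(sprintf("  accuracy: mean %.3f, sd %.3f, 95%% CI [%.3f, %.3f] over %d subject(s)\n",
              object@mean, object@sd, object@ci95[1L], object@ci95[2L],
              length(object@perSubjectAccuracy)))
  cat(sprintf("  chance level: %.3f; folds: %s\n", object@chanceLevel,
              paste(sprintf("%.3f", object@perFoldAccuracy), collapse = ", ")))
})

setMethod("show", "ComparisonReport", function(object) {
  a <- object@anova
  cat(sprintf("ComparisonReport (control: %s)\n", object@control))
  cat(sprintf("  one-way ANOVA: F(%g, %g) = %.3f, p = %.4g\n",
              a$dfBetween, a$dfWithin, a$F, a$p))
  if (nrow(object@dunnett)) {
    cat("  Dunnett many-to-one comparisons:\n")
    d <- object@dunnett
    stars <- ifelse(d$p.adjusted < 0.01, "**",
                    ifelse(d$p.adjusted < 0.05, "*", ""))
    for (i in seq_len(nrow(d)))
      cat(sprintf("    %-20s diff %+ .4f  t = %+ .3f  p.adj = %.4g %s\n",
                  d$comparison[i], d$mean.diff[i], d$t[i], d$p.adjusted[i],
                  stars[i]))
  }
  if (nrow(object@pairedT)) {
    cat("  paired t-tests:\n")
    for (i in seq_len(nrow(object@pairedT)))
      cat(sprintf("    %-20s t = %+ .3f (df %g)  p = %.4g\n",
                  object@pairedT$comparison[i], object@pairedT$t[i],
                  object@pairedT$df[i], object@pairedT$p[i]))
  }
})
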