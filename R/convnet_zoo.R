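#' Convert a kernel duration to samples
#'
#' Kernels are specified as durations in milliseconds so that the same
#' receptive time scales carry across datasets with different sampling
#' rates; they are converted to sample counts per dataset.  Nearest-integer
#' rounding with ties rounding up, minimum one sample.
#'
#' @param ms duration(s), milliseconds.
#' @param fs sampling rate, Hz.
#' @return integer sample count(s).
#' @examples
#' msToSamples(c(25, 50, 100, 200), 200)  # 5 10 20 40
#' msToSamples(25, 128)                   # 3
#' @export
msToSamples <- function(ms, fs) {
  stopifnot(all(ms > 0), fs > 0)
  pmax(1L, as.integer(floor(ms * fs / 1000 + 0.5)))
}

headUnits <- function(nClasses) if (nClasses == 2L) 1L else nClasses

newModelSpec <- function(family, fs, windowS, nChannels, nClasses,
                         branchKernelsMs = numeric(),
                         filtersPerBranch = 0L, featureMultiplier = 2L,
                         spatialFilters = 0L, seRatio = 16L,
                         useSE = FALSE, batchNorm = TRUE,
                         temporalKernelMs = 0, sepKernelMs = 0,
                         blockFilters = integer(), poolSpec = list(),
                         dropout = 0, reformed = FALSE, seed = 1L) {
  new("ModelSpec", family = family, fs = as.numeric(fs),
      windowS = as.numeric(windowS), nChannels = as.integer(nChannels),
      nClasses = as.integer(nClasses),
      branchKernelsMs = as.numeric(branchKernelsMs),
      filtersPerBranch = as.integer(filtersPerBranch),
      featureMultiplier = as.integer(featureMultiplier),
      spatialFilters = as.integer(spatialFilters),
      seRatio = as.integer(seRatio), useSE = useSE, batchNorm = batchNorm,
      temporalKernelMs = as.numeric(temporalKernelMs),
      sepKernelMs = as.numeric(sepKernelMs),
      blockFilters = as.integer(blockFilters), poolSpec = poolSpec,
      dropout = as.numeric(dropout), reformed = reformed,
      seed = as.integer(seed))
}

#' MultiT-S ConvNet architecture spec
#'
#' The multi-kernel temporal and spatial convolution network: four parallel
#' temporal convolutions with kernel durations 25/50/100/200 ms (zero-padded
#' "same", ReLU, shared average pooling, concatenated to Fte maps), a
#' squeeze-and-excitation (SE) recalibration of the temporal maps, a
#' depthwise-separable spatial convolution (feature multiplier 2 across the
#' full electrode span, pointwise mix to Fsp maps), SE recalibration of the
#' spatial maps, and a compact affine classifier head.
#'
#' Defaults give the canonical SEED-configuration model: 2 s window at
#' 200 Hz over 62 channels, 24 filters per branch (Fte = 96), Fsp = 64,
#' SE ratio 16, average pooling of length 4 after the temporal and spatial
#' stages, binary head — 30,313 trainable parameters.
#'
#' @param fs sampling rate, Hz.
#' @param windowS input window, seconds.
#' @param nChannels electrode count (62 canonical; 64 supported).
#' @param nClasses 2 or 3.
#' @param branchKernelsMs branch kernel durations, ms.
#' @param filtersPerBranch temporal filters per branch.
#' @param featureMultiplier depthwise spatial filters per temporal map.
#' @param spatialFilters pointwise output width Fsp.
#' @param seRatio SE bottleneck ratio r.
#' @param useSE include the two SE blocks.
#' @param batchNorm include batch-normalisation stages.
#' @param poolTemporal,poolSpatial average-pooling lengths.
#' @param seed weight-initialisation seed.
#' @return a [ModelSpec-class].
#' @seealso [buildModel()], [countParamsClosedForm()], [multikernelify()]
#' @export
multitsSpec <- function(fs = 200, windowS = 2, nChannels = 62L,
                        nClasses = 2L,
                        branchKernelsMs = c(25, 50, 100, 200),
                        filtersPerBranch = 24L, featureMultiplier = 2L,
                        spatialFilters = 64L, seRatio = 16L, useSE = TRUE,
                        batchNorm = TRUE, poolTemporal = 4L,
                        poolSpatial = 4L, seed = 1L) {
  newModelSpec("multits", fs, windowS, nChannels, nClasses,
               branchKernelsMs = branchKernelsMs,
               filtersPerBranch = filtersPerBranch,
               featureMultiplier = featureMultiplier,
               spatialFilters = spatialFilters, seRatio = seRatio,
               useSE = useSE, batchNorm = batchNorm,
               poolSpec = list(temporal = as.integer(poolTemporal),
                               spatial = as.integer(poolSpatial)),
               seed = seed)
}

#' Deep ConvNet architecture spec
#'
#' The deep EEG decoding network: a temporal convolution, a full spatial
#' convolution over all electrodes, then three temporal conv-pool blocks of
#' growing width, and an affine head.  Filter counts default to
#' 24/24/48/96/192 with 30 ms (6-sample at 200 Hz) kernels, valid padding
#' and max-pooling of length 3 — 182,497 trainable parameters at the SEED
#' input.
#'
#' @inheritParams multitsSpec
#' @param temporalKernelMs kernel duration of every conv layer, ms.
#' @param blockFilters filter counts: temporal, spatial, then the three
#'   conv-pool blocks.
#' @param poolLen max-pooling length (stride equal).
#' @return a [ModelSpec-class].
#' @export
deepConvNetSpec <- function(fs = 200, windowS = 2, nChannels = 62L,
                            nClasses = 2L, temporalKernelMs = 30,
                            blockFilters = c(24L, 24L, 48L, 96L, 192L),
                            poolLen = 3L, batchNorm = TRUE, seed = 1L) {
  newModelSpec("deep", fs, windowS, nChannels, nClasses,
               temporalKernelMs = temporalKernelMs,
               blockFilters = blockFilters, batchNorm = batchNorm,
               poolSpec = list(pool = as.integer(poolLen)), seed = seed)
}

#' Shallow ConvNet architecture spec
#'
#' The band-power-inspired shallow network: one temporal convolution
#' (50 ms kernel), one spatial convolution over all electrodes, squaring,
#' average pooling (length 50, stride 10 samples) and a log nonlinearity
#' before the affine head.  Defaults (40/40 filters) give 101,281
#' trainable parameters at the SEED input.
#'
#' @inheritParams deepConvNetSpec
#' @param poolLenSamples,poolStrideSamples average-pooling geometry, samples.
#' @return a [ModelSpec-class].
#' @export
shallowConvNetSpec <- function(fs = 200, windowS = 2, nChannels = 62L,
                               nClasses = 2L, temporalKernelMs = 50,
                               blockFilters = c(40L, 40L),
                               poolLenSamples = 50L, poolStrideSamples = 10L,
                               batchNorm = TRUE, seed = 1L) {
  newModelSpec("shallow", fs, windowS, nChannels, nClasses,
               temporalKernelMs = temporalKernelMs,
               blockFilters = blockFilters, batchNorm = batchNorm,
               poolSpec = list(len = as.integer(poolLenSamples),
                               stride = as.integer(poolStrideSamples)),
               seed = seed)
}

#' EEGNet architecture spec
#'
#' The compact separable-convolution network: a long temporal convolution
#' (half the sampling rate, 500 ms), a depthwise spatial convolution over
#' all electrodes with depth multiplier 2, then a separable temporal
#' convolution (depthwise 80 ms kernel + pointwise mix), with average
#' pooling 4 and 8 and dropout.  Defaults (32 temporal filters, 64 spatial
#' maps, 64 pointwise) give 13,537 trainable parameters at the SEED input.
#'
#' @inheritParams multitsSpec
#' @param temporalKernelMs first temporal kernel duration, ms.
#' @param sepKernelMs separable (depthwise) kernel duration, ms.
#' @param pool1,pool2 average-pooling lengths after the spatial and
#'   separable stages.
#' @param dropout dropout rate.
#' @return a [ModelSpec-class].
#' @export
eegnetSpec <- function(fs = 200, windowS = 2, nChannels = 62L,
                       nClasses = 2L, temporalKernelMs = 500,
                       filtersPerBranch = 32L, featureMultiplier = 2L,
                       spatialFilters = 64L, sepKernelMs = 80,
                       pool1 = 4L, pool2 = 8L, dropout = 0.25,
                       batchNorm = TRUE, seed = 1L) {
  newModelSpec("eegnet", fs, windowS, nChannels, nClasses,
               temporalKernelMs = temporalKernelMs,
               filtersPerBranch = filtersPerBranch,
               featureMultiplier = featureMultiplier,
               spatialFilters = spatialFilters, sepKernelMs = sepKernelMs,
               dropout = dropout, batchNorm = batchNorm,
               poolSpec = list(pool1 = as.integer(pool1),
                               pool2 = as.integer(pool2)), seed = seed)
}

#' Reform a single-kernel architecture with multi-kernel temporal filtering
#'
#' Replaces the temporal convolution of a Deep ConvNet, Shallow ConvNet or
#' EEGNet spec with the four-branch 25/50/100/200 ms multi-kernel block
#' (per-branch filters = half the original temporal filter count, so the
#' concatenated width doubles) and halves every downstream filter count to
#' preserve the parameter budget.  A batch-norm stage follows the
#' concatenation.  The reformed EEGNet's second pooling stage uses length
#' 14 (its published parameter budget pins the flattened width).
#'
#' @param spec a [ModelSpec-class] of family deep, shallow or eegnet.
#' @param branchKernelsMs branch durations, ms.
#' @return the reformed [ModelSpec-class] (`reformed = TRUE`).
#' @examples
#' sp <- multikernelify(deepConvNetSpec())
#' countParamsClosedForm(sp)  # 73777
#' @export
multikernelify <- function(spec, branchKernelsMs = c(25, 50, 100, 200)) {
  stopifnot(is(spec, "ModelSpec"))
  if (spec@family == "multits")
    stop("the MultiT-S family is already multi-kernel")
  if (isTRUE(spec@reformed))
    stop("spec is already reformed")
  out <- spec
  out@reformed <- TRUE
  out@branchKernelsMs <- as.numeric(branchKernelsMs)
  if (spec@family %in% c("deep", "shallow")) {
    out@filtersPerBranch <- as.integer(spec@blockFilters[1L] %/% 2L)
    out@blockFilters <- as.integer(pmax(1L, spec@blockFilters %/% 2L))
  } else {                                    # eegnet
    out@filtersPerBranch <- as.integer(spec@filtersPerBranch %/% 2L)
    out@spatialFilters <- as.integer(spec@spatialFilters %/% 2L)
    out@poolSpec$pool2 <- 14L
  }
  out
}

#' Lowest frequency fully covered by a model's temporal filters
#'
#' The lowest frequency that completes one full cycle inside the longest
#' temporal kernel: `fs / longest kernel length in samples`.
#'
#' @param spec a [ModelSpec-class].
#' @return frequency in Hz.
#' @examples
#' minFrequencyCovered(multitsSpec())            # 5 (40-sample kernel)
#' minFrequencyCovered(eegnetSpec())             # 2 (100-sample kernel)
#' @export
minFrequencyCovered <- function(spec) {
  stopifnot(is(spec, "ModelSpec"))
  kmax <- if (length(spec@branchKernelsMs))
    max(msToSamples(spec@branchKernelsMs, spec@fs))
  else max(msToSamples(spec@temporalKernelMs, spec@fs))
  spec@fs / kmax
}

# ---- stage descriptors (module surface for the building blocks) --------

#' Architecture building blocks
#'
#' Stage descriptors for the network's building blocks: each returns the
#' list of engine layers plus the output stage shape
#' `(time, space, features)` given an input shape.  [buildModel()]
#' assembles these; they are exposed so that stages can be inspected and
#' composed independently.
#'
#' `multikernelTemporalBlock`: four (or `length(kernels)`) parallel
#' zero-padded temporal convolutions with optional ReLU and shared average
#' pooling, concatenated on the feature axis (Fte = filters x branches).
#' `seBlock`: squeeze (global average) -> bottleneck
#' `max(1, floor(f / r))` with ReLU -> expansion with sigmoid gates in
#' (0, 1) multiplying the input per feature.
#' `separableSpatialBlock`: depthwise spatial filters spanning all
#' electrodes (`featureMultiplier` per temporal map, collapsing space to
#' 1) followed by a pointwise mix to `spatialFilters` maps.
#' `classifierHead`: flatten plus a single affine map; 1 sigmoid unit for
#' 2 classes, 3 softmax units for 3.
#'
#' @param spec a [ModelSpec-class].
#' @param inShape numeric `c(time, space, features)` at block input.
#' @param f,r SE feature count and ratio.
#' @param nClasses 2 or 3.
#' @param relu,pool branch activation / pooling of the temporal block.
#' @return list with `layers` (engine layer list), `outShape`, and for the
#'   SE block `bottleneck`.
#' @name buildingBlocks
NULL

#' @rdname buildingBlocks
#' @export
multikernelTemporalBlock <- function(spec, inShape = NULL, relu = TRUE,
                                     pool = NULL) {
  kern <- msToSamples(spec@branchKernelsMs, spec@fs)
  if (is.null(inShape))
    inShape <- c(round(spec@windowS * spec@fs), spec@nChannels, 1)
  if (is.null(pool))
    pool <- if (!is.null(spec@poolSpec$temporal)) spec@poolSpec$temporal else 1L
  m <- spec@filtersPerBranch
  lyr <- layerBranchConv(kern, fin = inShape[3L], m = m, pad = "same",
                         bias = TRUE, relu = relu, pool = pool)
  tOut <- if (pool > 1L) poolOutLen(inShape[1L], pool, pool) else inShape[1L]
  list(layers = list(lyr),
       outShape = c(tOut, inShape[2L], m * length(kern)))
}

#' @rdname buildingBlocks
#' @export
seBlock <- function(f, r) {
  lyr <- layerSE(f, r, bias = FALSE)
  list(layers = list(lyr), outShape = NULL, bottleneck = lyr$h)
}

#' @rdname buildingBlocks
#' @export
separableSpatialBlock <- function(spec, inShape) {
  E <- inShape[2L]; fin <- inShape[3L]; D <- spec@featureMultiplier
  if (E != spec@nChannels)
    stop("spatial block expects the full electrode span at its input")
  layers <- list(layerSpatialDW(E, fin, D, bias = TRUE))
  shapes <- c(inShape[1L], 1, fin * D)
  layers <- c(layers, list(layerPWConv(fin * D, spec@spatialFilters)))
  list(layers = layers,
       outShape = c(inShape[1L], 1, spec@spatialFilters),
       depthwiseFeatures = fin * D)
}

#' @rdname buildingBlocks
#' @export
classifierHead <- function(nClasses, inShape = NULL) {
  if (!nClasses %in% c(2L, 3L)) stop("only 2- or 3-class heads are supported")
  u <- headUnits(nClasses)
  layers <- list(layerFlatten())
  if (!is.null(inShape))
    layers <- c(layers, list(layerDense(prod(inShape), u)))
  list(layers = layers, outShape = c(1, 1, u), units = u)
}

# ---- model building ----------------------------------------------------

#' Built EEG ConvNet
#'
#' A trainable network built from a [ModelSpec-class]: the engine layer
#' list plus the per-stage shape trace recorded during construction.
#'
#' @slot spec the [ModelSpec-class] the model was built from.
#' @slot layers engine layer list (weights included).
#' @slot trace data.frame of per-stage shapes `(stage, time, space,
#'   features)`.
#' @seealso [buildModel()], [countTrainableParams()]
#' @export
setClass("EEGConvNet",
  representation(spec = "ModelSpec", layers = "list", trace = "data.frame"))

setMethod("show", "EEGConvNet", function(object) {
  cat("EEGConvNet built from:\n")
  show(object@spec)
  cat(sprintf("  %d engine layer(s); built parameter count %s\n",
              length(object@layers),
              format(countTrainableParams(object), big.mark = ",")))
  print(object@trace, row.names = FALSE)
})

addStage <- function(state, stage, layers, shape) {
  state$layers <- c(state$layers, layers)
  state$stageOf <- c(state$stageOf, rep(stage, length(layers)))
  state$trace <- rbind(state$trace,
                       data.frame(stage = stage, time = shape[1L],
                                  space = shape[2L], features = shape[3L]))
  state$shape <- shape
  state
}

#' Build a trainable model from an architecture spec
#'
#' Instantiates all weights (Glorot-uniform, seeded from the spec) and
#' records the per-stage shape trace.  Construction fails with the name of
#' the offending stage if pooling exhausts the time axis.
#'
#' @param spec a [ModelSpec-class].
#' @return an [EEGConvNet-class].
#' @examples
#' net <- buildModel(multitsSpec(nChannels = 8L, filtersPerBranch = 4L,
#'                               spatialFilters = 8L))
#' countTrainableParams(net)
#' @export
buildModel <- function(spec) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  set.seed(spec@seed)
  Tw <- as.integer(round(spec@windowS * spec@fs))
  E <- spec@nChannels
  st <- list(layers = list(), stageOf = character(),
             trace = data.frame(), shape = c(Tw, E, 1))
  st <- addStage(st, "input", list(), c(Tw, E, 1))

  bn <- function(state, f, stage) {
    if (!spec@batchNorm) return(state)
    addStage(state, stage, list(layerBatchNorm(f)), state$shape)
  }

  fam <- spec@family
  if (fam == "multits" || isTRUE(spec@reformed)) {
    relu <- fam == "multits"
    pool <- if (fam == "multits") spec@poolSpec$temporal else 1L
    blk <- multikernelTemporalBlock(spec, st$shape, relu = relu, pool = pool)
    st <- addStage(st, "multikernel_temporal", blk$layers, blk$outShape)
    fte <- blk$outShape[3L]
    st <- bn(st, fte, "temporal_bn")
  }

  if (fam == "multits") {
    if (spec@useSE) {
      se1 <- seBlock(st$shape[3L], spec@seRatio)
      st <- addStage(st, "temporal_se", se1$layers, st$shape)
    }
    sp <- separableSpatialBlock(spec, st$shape)
    st <- addStage(st, "spatial_depthwise", sp$layers[1L],
                   c(st$shape[1L], 1, sp$depthwiseFeatures))
    st <- bn(st, sp$depthwiseFeatures, "depthwise_bn")
    st <- addStage(st, "spatial_pointwise", sp$layers[2L], sp$outShape)
    st <- bn(st, st$shape[3L], "spatial_bn")
    st <- addStage(st, "spatial_act", list(layerAct("relu")), st$shape)
    p <- spec@poolSpec$spatial
    if (p > 1L) {
      tOut <- poolOutLen(st$shape[1L], p, p)
      st <- addStage(st, "spatial_pool", list(layerPool("avgpool", p)),
                     c(tOut, st$shape[2L], st$shape[3L]))
    }
    if (spec@useSE) {
      se2 <- seBlock(st$shape[3L], spec@seRatio)
      st <- addStage(st, "spatial_se", se2$layers, st$shape)
    }
  } else if (fam == "deep") {
    k <- msToSamples(spec@temporalKernelMs, spec@fs)
    bf <- spec@blockFilters
    pool <- spec@poolSpec$pool
    if (!isTRUE(spec@reformed)) {
      st <- addStage(st, "temporal_conv",
                     list(layerTConv(k, 1L, bf[1L], pad = "valid")),
                     c(st$shape[1L] - k + 1L, E, bf[1L]))
    }
    fin <- st$shape[3L]
    st <- addStage(st, "spatial_conv",
                   list(layerSpatialConv(E, fin, bf[2L])),
                   c(st$shape[1L], 1, bf[2L]))
    st <- bn(st, bf[2L], "spatial_bn")
    st <- addStage(st, "block1_act_pool",
                   list(layerAct("elu"), layerPool("maxpool", pool)),
                   c(poolOutLen(st$shape[1L], pool), 1, bf[2L]))
    for (i in 3:length(bf)) {
      tConv <- st$shape[1L] - k + 1L
      if (tConv < 1L)
        stop("conv block ", i - 2L, " exhausts the time axis")
      st <- addStage(st, paste0("block", i - 1L, "_conv"),
                     list(layerTConv(k, st$shape[3L], bf[i], pad = "valid")),
                     c(tConv, 1, bf[i]))
      st <- bn(st, bf[i], paste0("block", i - 1L, "_bn"))
      st <- addStage(st, paste0("block", i - 1L, "_act_pool"),
                     list(layerAct("elu"), layerPool("maxpool", pool)),
                     c(poolOutLen(st$shape[1L], pool), 1, bf[i]))
    }
  } else if (fam == "shallow") {
    k <- msToSamples(spec@temporalKernelMs, spec@fs)
    bf <- spec@blockFilters
    if (!isTRUE(spec@reformed)) {
      st <- addStage(st, "temporal_conv",
                     list(layerTConv(k, 1L, bf[1L], pad = "same")),
                     c(st$shape[1L], E, bf[1L]))
      st <- bn(st, bf[1L], "temporal_bn")
    }
    st <- addStage(st, "spatial_conv",
                   list(layerSpatialConv(E, st$shape[3L], bf[2L])),
                   c(st$shape[1L], 1, bf[2L]))
    st <- bn(st, bf[2L], "spatial_bn")
    len <- spec@poolSpec$len; stride <- spec@poolSpec$stride
    tOut <- poolOutLen(st$shape[1L], len, stride)
    st <- addStage(st, "square_pool_log",
                   list(layerAct("square"),
                        layerPool("avgpool", len, stride),
                        layerAct("logeps")),
                   c(tOut, 1, bf[2L]))
  } else if (fam == "eegnet") {
    D <- spec@featureMultiplier
    if (!isTRUE(spec@reformed)) {
      k1 <- msToSamples(spec@temporalKernelMs, spec@fs)
      st <- addStage(st, "temporal_conv",
                     list(layerTConv(k1, 1L, spec@filtersPerBranch,
                                     pad = "same")),
                     c(st$shape[1L], E, spec@filtersPerBranch))
      st <- bn(st, spec@filtersPerBranch, "temporal_bn")
    }
    fin <- st$shape[3L]
    st <- addStage(st, "spatial_depthwise",
                   list(layerSpatialDW(E, fin, D)),
                   c(st$shape[1L], 1, fin * D))
    st <- bn(st, fin * D, "spatial_bn")
    p1 <- spec@poolSpec$pool1
    st <- addStage(st, "spatial_act_pool",
                   list(layerAct("elu"), layerPool("avgpool", p1),
                        layerDropout(spec@dropout)),
                   c(poolOutLen(st$shape[1L], p1), 1, fin * D))
    ks <- msToSamples(spec@sepKernelMs, spec@fs)
    st <- addStage(st, "separable_depthwise",
                   list(layerDWTConv(ks, st$shape[3L], bias = FALSE)),
                   st$shape)
    st <- addStage(st, "separable_pointwise",
                   list(layerPWConv(st$shape[3L], spec@spatialFilters)),
                   c(st$shape[1L], 1, spec@spatialFilters))
    st <- bn(st, spec@spatialFilters, "separable_bn")
    p2 <- spec@poolSpec$pool2
    st <- addStage(st, "separable_act_pool",
                   list(layerAct("elu"), layerPool("avgpool", p2),
                        layerDropout(spec@dropout)),
                   c(poolOutLen(st$shape[1L], p2), 1, spec@spatialFilters))
  }

  head <- classifierHead(spec@nClasses, st$shape)
  st <- addStage(st, "classifier", head$layers, c(1, 1, head$units))

  names(st$layers) <- make.unique(st$stageOf, sep = "#")
  new("EEGConvNet", spec = spec, layers = st$layers, trace = st$trace)
}

#' Count trainable parameters of a built model
#'
#' Counts the optimisable scalars actually instantiated in the built
#' network (weights, biases, batch-norm scale/shift; batch-norm running
#' statistics are excluded).  The independent closed-form route is
#' [countParamsClosedForm()].
#'
#' @param model an [EEGConvNet-class].
#' @return integer parameter count.
#' @examples
#' countTrainableParams(buildModel(eegnetSpec()))  # 13537
#' @export
countTrainableParams <- function(model) {
  stopifnot(is(model, "EEGConvNet"))
  countLayerParams(model@layers)
}

#' Per-stage parameter table of a built model
#'
#' @param model an [EEGConvNet-class].
#' @return data.frame with one row per named stage and its parameter count.
#' @export
paramTable <- function(model) {
  stopifnot(is(model, "EEGConvNet"))
  counts <- vapply(model@layers, function(l)
    sum(vapply(l$params, function(p) if (is.null(p)) 0L else length(p),
               integer(1))), integer(1))
  stage <- sub("#.*$", "", names(model@layers))
  agg <- tapply(counts, factor(stage, levels = unique(stage)), sum)
  data.frame(stage = names(agg), parameters = as.integer(agg),
             row.names = NULL)
}

#' Closed-form trainable-parameter count from a spec
#'
#' Computes the trainable-parameter total analytically from the
#' architecture description alone, per-stage, without instantiating any
#' weights.  Serves as the independent cross-check of
#' [countTrainableParams()] (the two must agree exactly).
#'
#' @param spec a [ModelSpec-class].
#' @return integer parameter count.
#' @examples
#' countParamsClosedForm(multitsSpec())      # 30313
#' countParamsClosedForm(deepConvNetSpec())  # 182497
#' @export
countParamsClosedForm <- function(spec) {
  stopifnot(is(spec, "ModelSpec"))
  Tw <- as.integer(round(spec@windowS * spec@fs))
  E <- spec@nChannels
  u <- headUnits(spec@nClasses)
  bnp <- function(f) if (spec@batchNorm) 2L * f else 0L
  pOut <- function(t, len, stride = len) (t - len) %/% stride + 1L
  fam <- spec@family
  total <- 0L

  if (fam == "multits") {
    kern <- msToSamples(spec@branchKernelsMs, spec@fs)
    m <- spec@filtersPerBranch
    fte <- m * length(kern)
    D <- spec@featureMultiplier
    fsp <- spec@spatialFilters
    total <- total + sum(kern * m) + m * length(kern)          # branches
    total <- total + bnp(fte)
    if (spec@useSE) {
      h <- max(1L, fte %/% spec@seRatio)
      total <- total + fte * h + h * fte
    }
    total <- total + E * fte * D + fte * D                     # depthwise
    total <- total + bnp(fte * D)
    total <- total + fte * D * fsp + fsp                       # pointwise
    total <- total + bnp(fsp)
    if (spec@useSE) {
      h2 <- max(1L, fsp %/% spec@seRatio)
      total <- total + fsp * h2 + h2 * fsp
    }
    t1 <- pOut(Tw, spec@poolSpec$temporal)
    t2 <- pOut(t1, spec@poolSpec$spatial)
    total <- total + fsp * t2 * u + u
  } else if (fam == "deep") {
    k <- msToSamples(spec@temporalKernelMs, spec@fs)
    bf <- spec@blockFilters
    pool <- spec@poolSpec$pool
    if (isTRUE(spec@reformed)) {
      kern <- msToSamples(spec@branchKernelsMs, spec@fs)
      m <- spec@filtersPerBranch
      fte <- m * length(kern)
      total <- total + sum(kern * m) + fte + bnp(fte)
      t <- Tw
    } else {
      fte <- bf[1L]
      total <- total + k * bf[1L] + bf[1L]
      t <- Tw - k + 1L
    }
    total <- total + E * fte * bf[2L] + bf[2L] + bnp(bf[2L])
    t <- pOut(t, pool)
    prev <- bf[2L]
    for (i in 3:length(bf)) {
      total <- total + k * prev * bf[i] + bf[i] + bnp(bf[i])
      t <- pOut(t - k + 1L, pool)
      prev <- bf[i]
    }
    total <- total + prev * t * u + u
  } else if (fam == "shallow") {
    k <- msToSamples(spec@temporalKernelMs, spec@fs)
    bf <- spec@blockFilters
    if (isTRUE(spec@reformed)) {
      kern <- msToSamples(spec@branchKernelsMs, spec@fs)
      m <- spec@filtersPerBranch
      fte <- m * length(kern)
      total <- total + sum(kern * m) + fte + bnp(fte)
    } else {
      fte <- bf[1L]
      total <- total + k * bf[1L] + bf[1L] + bnp(bf[1L])
    }
    total <- total + E * fte * bf[2L] + bf[2L] + bnp(bf[2L])
    t <- pOut(Tw, spec@poolSpec$len, spec@poolSpec$stride)
    total <- total + bf[2L] * t * u + u
  } else if (fam == "eegnet") {
    D <- spec@featureMultiplier
    f2 <- spec@spatialFilters
    ks <- msToSamples(spec@sepKernelMs, spec@fs)
    if (isTRUE(spec@reformed)) {
      kern <- msToSamples(spec@branchKernelsMs, spec@fs)
      m <- spec@filtersPerBranch
      f1 <- m * length(kern)
      total <- total + sum(kern * m) + f1 + bnp(f1)
    } else {
      k1 <- msToSamples(spec@temporalKernelMs, spec@fs)
      f1 <- spec@filtersPerBranch
      total <- total + k1 * f1 + f1 + bnp(f1)
    }
    total <- total + E * f1 * D + f1 * D + bnp(f1 * D)         # depthwise
    total <- total + ks * f1 * D                               # sep depthwise
    total <- total + f1 * D * f2 + f2 + bnp(f2)                # pointwise
    t <- pOut(pOut(Tw, spec@poolSpec$pool1), spec@poolSpec$pool2)
    total <- total + f2 * t * u + u
  }
  as.integer(total)
}

#' Shape trace of a built model measured on a real forward pass
#'
#' Runs a zero input through the network and records the actual tensor
#' shape after every named stage; the construction-time trace
#' (`model@trace`) must agree with this measured trace.
#'
#' @param model an [EEGConvNet-class].
#' @param batch batch size of the probe input.
#' @return data.frame like `model@trace`.
#' @export
measuredTrace <- function(model, batch = 2L) {
  spec <- model@spec
  Tw <- as.integer(round(spec@windowS * spec@fs))
  x <- array(0, dim = c(1L, Tw, spec@nChannels, batch))
  stage <- sub("#.*$", "", names(model@layers))
  rows <- data.frame(stage = "input", time = Tw, space = spec@nChannels,
                     features = 1)
  for (i in seq_along(model@layers)) {
    r <- layerForward(model@layers[[i]], x, training = FALSE)
    x <- r$y
    last <- i == length(model@layers) || stage[i + 1L] != stage[i]
    if (last) {
      d <- if (is.matrix(x)) c(nrow(x), 1L, 1L) else dim(x)
      sh <- if (is.matrix(x)) c(1L, 1L, nrow(x)) else d[c(2L, 3L, 1L)]
      rows <- rbind(rows, data.frame(stage = stage[i], time = sh[1L],
                                     space = sh[2L], features = sh[3L]))
    }
  }
  rows
}
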