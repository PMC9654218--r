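test_that("kernel durations convert to samples with nearest-integer rounding", {
  expect_equal(msToSamples(c(25, 50, 100, 200), 200), c(5L, 10L, 20L, 40L))
  expect_equal(msToSamples(25, 128), 3L)
  expect_equal(msToSamples(2.5, 200), 1L)     # 0.5 rounds up
  expect_equal(msToSamples(0.1, 200), 1L)     # floor of one sample
})

test_that("the multi-kernel block concatenates Fte maps and preserves time", {
  sp <- multitsSpec()
  blk <- multikernelTemporalBlock(sp, pool = 1L)
  expect_equal(blk$outShape[3L], 96)          # 24 x 4 branches
  expect_equal(blk$outShape[1L], 400)         # same padding keeps T
  expect_equal(blk$layers[[1L]]$kernels, c(5L, 10L, 20L, 40L))

  # branch time dims always agree (they share the same-padded input), so
  # concatenation is well defined for any kernel set
  sp2 <- multitsSpec(branchKernelsMs = c(10, 35, 410), fs = 128)
  blk2 <- multikernelTemporalBlock(sp2, pool = 1L)
  x <- array(rnorm(1 * 256 * 2 * 3), c(1, 256, 2, 3))
  y <- multits:::layerForward(blk2$layers[[1L]], x, FALSE)$y
  expect_equal(dim(y), c(3 * 24, 256, 2, 3))
})

test_that("a unit single-branch block reduces to ReLU of the input", {
  lyr <- multits:::layerBranchConv(1L, fin = 1L, m = 1L, relu = TRUE,
                                   pool = 1L)
  lyr$params$W1[] <- 1
  lyr$params$b1[] <- 0
  set.seed(13)
  x <- array(rnorm(1 * 20 * 3 * 2), c(1, 20, 3, 2))
  y <- multits:::layerForward(lyr, x, FALSE)$y
  expect_equal(as.vector(y), as.vector(pmax(x, 0)))
})

test_that("SE bottleneck width, neutral gates and saturation limits", {
  expect_equal(seBlock(96, 16)$bottleneck, 6L)
  expect_equal(seBlock(3, 16)$bottleneck, 1L)   # floor with minimum 1

  set.seed(14)
  x <- array(rnorm(4 * 10 * 1 * 3), c(4, 10, 1, 3))
  # zero second dense layer -> every gate sigmoid(0) = 0.5 -> y = x/2
  se <- multits:::layerSE(4L, 2L, bias = FALSE)
  se$params$W2[] <- 0
  y <- multits:::layerForward(se, x, FALSE)$y
  expect_equal(y, x / 2)

  # large positive bias on the expansion -> gates ~ 1 -> y ~ x
  seb <- multits:::layerSE(4L, 2L, bias = TRUE)
  seb$params$b2[] <- 50
  yb <- multits:::layerForward(seb, x, FALSE)$y
  expect_equal(yb, x, tolerance = 1e-10)
})

test_that("SE gates stay strictly inside (0,1) and never amplify a feature", {
  set.seed(15)
  for (rep in 1:5) {
    f <- sample(3:12, 1)
    se <- multits:::layerSE(f, sample(2:4, 1), bias = FALSE)
    x <- array(rnorm(f * 8 * 2 * 3), c(f, 8, 2, 3))
    fw <- multits:::layerForward(se, x, FALSE)
    expect_true(all(fw$cache$g > 0 & fw$cache$g < 1))
    expect_true(all(abs(fw$y) <= abs(x) + 1e-12))
  }
})

test_that("the separable spatial block widens then mixes as specified", {
  sp <- multitsSpec()
  blk <- separableSpatialBlock(sp, c(100, 62, 96))
  expect_equal(blk$depthwiseFeatures, 192)    # Fte x multiplier 2
  expect_equal(blk$outShape, c(100, 1, 64))   # Fsp = 64
  expect_error(separableSpatialBlock(sp, c(100, 10, 96)), "electrode")
})

test_that("one-hot depthwise weights route a single channel through the block", {
  # depthwise selects channel 1 per map; pointwise selects map 1 -> the
  # output must equal channel 1's first temporal feature map
  E <- 4L; fin <- 3L
  dw <- multits:::layerSpatialDW(E, fin, 1L, bias = TRUE)
  dw$params$W[] <- 0
  for (f in seq_len(fin)) dw$params$W[1L, f, 1L] <- 1
  dw$params$b[] <- 0
  pw <- multits:::layerPWConv(fin, 1L)
  pw$params$W[] <- 0; pw$params$W[1L, 1L] <- 1; pw$params$b[] <- 0
  set.seed(16)
  x <- array(rnorm(fin * 12 * E * 2), c(fin, 12, E, 2))
  h <- multits:::layerForward(dw, x, FALSE)$y
  y <- multits:::layerForward(pw, h, FALSE)$y
  expect_equal(as.vector(y[1L, , 1L, ]), as.vector(x[1L, , 1L, ]))
})

test_that("classifier heads have the prescribed widths and softmax(0) is uniform", {
  expect_equal(classifierHead(2L)$units, 1L)
  expect_equal(classifierHead(3L)$units, 3L)
  expect_error(classifierHead(4L), "2- or 3-class")

  dense <- multits:::layerDense(6L, 3L)
  dense$params$W[] <- 0; dense$params$b[] <- 0
  out <- multits:::layerForward(dense, matrix(rnorm(12), 6L), FALSE)$y
  p <- exp(out) / rep(colSums(exp(out)), each = 3L)
  expect_equal(as.vector(p), rep(1 / 3, 6))
})

test_that("built models expose the canonical first-stage kernels and widths", {
  net <- buildModel(multitsSpec())
  expect_equal(net@layers[[1L]]$kernels, c(5L, 10L, 20L, 40L))

  enet <- buildModel(eegnetSpec())
  tr <- enet@trace
  expect_equal(tr$features[tr$stage == "temporal_conv"], 32)
  expect_equal(tr$features[tr$stage == "spatial_depthwise"], 64)
  expect_equal(tr$features[tr$stage == "separable_pointwise"], 64)
})

test_that("every family forward-passes zeros to finite outputs of head width", {
  specs <- list(multitsSpec(), deepConvNetSpec(), shallowConvNetSpec(),
                eegnetSpec(), multikernelify(deepConvNetSpec()),
                multikernelify(shallowConvNetSpec()),
                multikernelify(eegnetSpec()),
                multitsSpec(nClasses = 3L))
  for (sp in specs) {
    net <- buildModel(sp)
    x <- array(0, c(1, round(sp@windowS * sp@fs), sp@nChannels, 2))
    out <- multits:::nnForward(net@layers, x, training = FALSE)$out
    expect_true(all(is.finite(out)))
    expect_equal(nrow(out), if (sp@nClasses == 2L) 1L else 3L)
    expect_equal(ncol(out), 2L)
  }
})

test_that("construction-time shape traces equal the measured forward traces", {
  specs <- list(multitsSpec(), deepConvNetSpec(), shallowConvNetSpec(),
                eegnetSpec(), multikernelify(eegnetSpec()))
  for (sp in specs) {
    net <- buildModel(sp)
    m <- measuredTrace(net)
    expect_equal(net@trace$time, m$time, label = sp@family)
    expect_equal(net@trace$space, m$space)
    expect_equal(net@trace$features, m$features)
  }
})

test_that("the multi-kernel reform halves filters per the published scheme", {
  dp <- multikernelify(deepConvNetSpec())
  expect_equal(dp@filtersPerBranch, 12L)              # 12 x 4 = 48
  expect_equal(dp@blockFilters, c(12L, 12L, 24L, 48L, 96L))

  ep <- multikernelify(eegnetSpec())
  expect_equal(ep@filtersPerBranch, 16L)              # 16 x 4 = 64
  expect_equal(ep@spatialFilters, 32L)

  shp <- multikernelify(shallowConvNetSpec())
  expect_equal(shp@filtersPerBranch, 20L)             # 20 x 4 = 80
  expect_equal(shp@blockFilters, c(20L, 20L))

  expect_error(multikernelify(multitsSpec()), "already multi-kernel")
  expect_error(multikernelify(dp), "already reformed")
})

test_that("a single affine map counts its weights plus bias", {
  expect_equal(multits:::countLayerParams(list(multits:::layerDense(10L, 1L))),
               11L)
})

test_that("framework counts equal closed-form counts on randomized specs", {
  set.seed(17)
  for (rep in 1:10) {
    fam <- sample(c("multits", "deep", "shallow", "eegnet"), 1)
    fs <- sample(c(100, 128, 200), 1)
    nCh <- sample(c(4L, 8L, 22L), 1)
    nCl <- sample(c(2L, 3L), 1)
    bn <- sample(c(TRUE, FALSE), 1)
    sp <- switch(fam,
      multits = multitsSpec(fs = fs, nChannels = nCh, nClasses = nCl,
                            filtersPerBranch = sample(2:8, 1),
                            spatialFilters = sample(c(8L, 16L), 1),
                            seRatio = sample(c(2L, 4L, 16L), 1),
                            batchNorm = bn,
                            useSE = sample(c(TRUE, FALSE), 1)),
      deep = deepConvNetSpec(fs = fs, nChannels = nCh, nClasses = nCl,
                             blockFilters = c(6L, 6L, 12L, 24L, 48L),
                             batchNorm = bn),
      shallow = shallowConvNetSpec(fs = fs, nChannels = nCh,
                                   nClasses = nCl, batchNorm = bn,
                                   blockFilters = c(10L, 10L)),
      eegnet = eegnetSpec(fs = fs, nChannels = nCh, nClasses = nCl,
                          filtersPerBranch = 8L, spatialFilters = 16L,
                          batchNorm = bn))
    if (sample(c(TRUE, FALSE), 1) && fam != "multits")
      sp <- multikernelify(sp)
    expect_equal(countTrainableParams(buildModel(sp)),
                 countParamsClosedForm(sp),
                 label = paste(fam, "fs", fs, "ch", nCh))
  }
})

test_that("minimum frequency covered is fs over the longest kernel", {
  expect_equal(minFrequencyCovered(multitsSpec()), 5)        # 40 samples
  expect_equal(minFrequencyCovered(eegnetSpec()), 2)         # 100 samples
  sp <- deepConvNetSpec(fs = 200, temporalKernelMs = 1000)   # kernel = fs
  expect_equal(minFrequencyCovered(sp), 1)
})

test_that("pooling that exhausts the time axis names the failing stage", {
  expect_error(buildModel(deepConvNetSpec(windowS = 0.15)), "block|time")
})
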