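# Finite-difference gradient checks of every layer kind, and Adam sanity.

numGrad <- function(fn, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

# scalar loss = weighted sum of the layer output, fixed random weights
checkLayerGrads <- function(layer, dims, tol = 1e-6, training = TRUE) {
  set.seed(42)
  x <- array(rnorm(prod(dims)), dim = dims)
  fw <- multits:::layerForward(layer, x, training)
  wsum <- array(rnorm(length(fw$y)), dim = dim(fw$y))
  loss <- function(xv) {
    xa <- array(xv, dim = dims)
    sum(multits:::layerForward(layer, xa, training)$y * wsum)
  }
  bk <- multits:::layerBackward(layer, fw$cache, wsum)
  expect_equal(as.vector(bk$dx), as.vector(numGrad(loss, as.vector(x))),
               tolerance = tol)
  for (nm in names(layer$params)) {
    p <- layer$params[[nm]]
    if (is.null(p)) next
    lossp <- function(pv) {
      l2 <- layer
      l2$params[[nm]] <- if (is.null(dim(p))) as.vector(pv)
                         else array(pv, dim = dim(p))
      sum(multits:::layerForward(l2, x, training)$y * wsum)
    }
    expect_equal(as.vector(bk$grads[[nm]]),
                 as.vector(numGrad(lossp, as.vector(p))),
                 tolerance = tol, label = paste("grad", layer$kind, nm))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("convolution, pooling and gating layers backpropagate exact gradients", {
  set.seed(7)
  dims <- c(3L, 12L, 4L, 2L)      # (F, T, S, B)
  checkLayerGrads(multits:::layerTConv(5L, 3L, 4L, pad = "same"), dims)
  checkLayerGrads(multits:::layerTConv(4L, 3L, 2L, pad = "valid"), dims)
  checkLayerGrads(multits:::layerBranchConv(c(3L, 5L), fin = 3L, m = 2L,
                                            relu = TRUE, pool = 2L), dims)
  checkLayerGrads(multits:::layerDWTConv(3L, 3L, bias = TRUE), dims)
  checkLayerGrads(multits:::layerSpatialConv(4L, 3L, 5L), dims)
  checkLayerGrads(multits:::layerSpatialDW(4L, 3L, 2L), dims)
  checkLayerGrads(multits:::layerPWConv(3L, 6L), dims)
  checkLayerGrads(multits:::layerSE(3L, 2L, bias = TRUE), dims)
  checkLayerGrads(multits:::layerSE(3L, 2L, bias = FALSE), dims)
  checkLayerGrads(multits:::layerBatchNorm(3L), dims, tol = 1e-5)
  checkLayerGrads(multits:::layerPool("avgpool", 3L), dims)
  checkLayerGrads(multits:::layerPool("avgpool", 4L, 2L), dims)
  checkLayerGrads(multits:::layerPool("maxpool", 3L), dims)
  checkLayerGrads(multits:::layerAct("relu"), dims)
  checkLayerGrads(multits:::layerAct("elu"), dims)
  checkLayerGrads(multits:::layerAct("square"), dims)
  d2 <- c(8L, 5L)                 # dense operates on (features, batch)
  set.seed(42)
  checkLayerGrads(multits:::layerDense(8L, 3L), d2)
})

test_that("log nonlinearity backpropagates on positive inputs", {
  set.seed(9)
  dims <- c(2L, 6L, 1L, 2L)
  x <- array(runif(prod(dims), 0.5, 2), dim = dims)
  layer <- multits:::layerAct("logeps")
  fw <- multits:::layerForward(layer, x, FALSE)
  wsum <- array(rnorm(length(fw$y)), dim = dim(fw$y))
  bk <- multits:::layerBackward(layer, fw$cache, wsum)
  loss <- function(xv) sum(multits:::layerForward(
    layer, array(xv, dim = dims), FALSE)$y * wsum)
  expect_equal(as.vector(bk$dx), as.vector(numGrad(loss, as.vector(x))),
               tolerance = 1e-6)
})

test_that("a full model's loss gradient matches finite differences", {
  sp <- multitsSpec(fs = 40, windowS = 1, nChannels = 3L,
                    filtersPerBranch = 2L, spatialFilters = 4L,
                    seRatio = 2L, poolTemporal = 2L, poolSpatial = 2L,
                    branchKernelsMs = c(50, 100), seed = 5L)
  net <- buildModel(sp)
  set.seed(8)
  x <- array(rnorm(1 * 40 * 3 * 4), c(1L, 40L, 3L, 4L))
  y <- c(1L, 2L, 2L, 1L)
  lossOf <- function(layers) {
    fw <- multits:::nnForward(layers, x, training = FALSE)
    multits:::lossGrad(fw$out, y, 2L)$loss
  }
  fw <- multits:::nnForward(net@layers, x, training = FALSE)
  lg <- multits:::lossGrad(fw$out, y, 2L)
  grads <- multits:::nnBackward(net@layers, fw$caches, lg$d)
  # probe a handful of weights spread over the network
  for (li in c(1L, 4L, 6L)) {
    nm <- names(net@layers[[li]]$params)[1L]
    p <- net@layers[[li]]$params[[nm]]
    for (j in c(1L, length(p))) {
      eps <- 1e-5
      lp <- net@layers; lp[[li]]$params[[nm]][j] <- p[j] + eps
      lm <- net@layers; lm[[li]]$params[[nm]][j] <- p[j] - eps
      num <- (lossOf(lp) - lossOf(lm)) / (2 * eps)
      expect_equal(grads[[li]][[nm]][j], num, tolerance = 1e-4)
    }
  }
})

test_that("Adam reduces the loss of a separable toy problem", {
  set.seed(3)
  layers <- list(multits:::layerDense(2L, 8L), multits:::layerAct("relu"),
                 multits:::layerDense(8L, 1L))
  n <- 60L
  X <- matrix(rnorm(2 * n), 2L)
  y <- as.integer(X[1L, ] + X[2L, ] > 0) + 1L
  state <- multits:::adamInit(layers)
  losses <- numeric(50)
  for (s in 1:50) {
    fw <- multits:::denseForwardAll(layers, X, TRUE)
    lg <- multits:::lossGrad(fw$out, y, 2L)
    losses[s] <- lg$loss
    gr <- multits:::denseBackwardAll(layers, fw$caches, lg$d)
    upd <- multits:::adamStep(layers, gr, state, 0.05, s)
    layers <- upd$layers; state <- upd$state
  }
  expect_lt(losses[50], losses[1] / 2)
})
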