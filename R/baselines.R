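#' Specification of a non-convolutional baseline classifier
#'
#' The three classical baselines evaluated on band-power features, with
#' fixed hyperparameters: K-nearest neighbours with 21 neighbours, random
#' forest with 100 trees, and a fully connected network with two hidden
#' layers of 100 logistic-sigmoid units trained with Adam.  Hyperparameters
#' are fixed at construction; the seed is recorded.
#'
#' @param kind `"knn"`, `"rf"` or `"fcn"`.
#' @param seed integer seed (rf and fcn are deterministic given the seed;
#'   knn is deterministic outright).
#' @param standardize z-score each feature column using training-fold
#'   statistics before fitting (leakage-safe; switchable off).
#' @param epochs,batch fcn training epochs and batch size.
#' @param lr fcn Adam step size.
#' @return object of class `BaselineSpec` (list).
#' @export
baselineSpec <- function(kind = c("knn", "rf", "fcn"), seed = 1L,
                         standardize = TRUE, epochs = 200L, batch = 100L,
                         lr = 1e-3) {
  kind <- match.arg(kind)
  hyper <- switch(kind,
    knn = list(k = 21L),
    rf = list(trees = 100L),
    fcn = list(hidden = c(100L, 100L), activation = "sigmoid",
               epochs = as.integer(epochs), batch = as.integer(batch),
               lr = lr))
  structure(list(kind = kind, hyperparams = hyper, seed = as.integer(seed),
                 standardize = standardize),
            class = "BaselineSpec")
}

#' @export
print.BaselineSpec <- function(x, ...) {
  cat(sprintf("BaselineSpec: %s (%s), seed %d\n", x$kind,
              paste(names(x$hyperparams),
                    vapply(x$hyperparams, function(h)
                      paste(h, collapse = "x"), character(1)),
                    sep = "=", collapse = ", "), x$seed))
  invisible(x)
}

#' Fit a baseline classifier
#'
#' @param spec a [baselineSpec()].
#' @param X numeric feature matrix (rows = epochs).
#' @param y class labels (factor or character).
#' @param Xval,yval optional validation split (used by the fcn for
#'   best-checkpoint selection; ignored by knn/rf).
#' @return fitted classifier for [predictBaseline()].
#' @export
fitBaseline <- function(spec, X, y, Xval = NULL, yval = NULL) {
  stopifnot(inherits(spec, "BaselineSpec"), nrow(X) == length(y))
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("degenerate training set: fewer than 2 classes present")
  ctr <- NULL; scl <- NULL
  if (spec$standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    X <- scale(X, center = ctr, scale = scl)
    if (!is.null(Xval)) Xval <- scale(Xval, center = ctr, scale = scl)
  }
  fit <- switch(spec$kind,
    knn = {
      k <- spec$hyperparams$k
      if (k > nrow(X)) {
        warning("k = ", k, " exceeds the ", nrow(X),
                " training rows; clamping k to the training size")
        k <- nrow(X)
      }
      list(X = X, y = y, k = k)
    },
    rf = {
      set.seed(spec$seed)
      randomForest::randomForest(x = X, y = y,
                                 ntree = spec$hyperparams$trees)
    },
    fcn = fitFCN(spec, X, y, Xval, yval)
  )
  structure(list(kind = spec$kind, fit = fit, levels = levels(y),
                 center = ctr, scale = scl, p = ncol(X)),
            class = "BaselineFit")
}

# two-hidden-layer logistic-sigmoid network trained with Adam on the
# package's engine (dense layers on (F, 1, 1, B) tensors)
fitFCN <- function(spec, X, y, Xval = NULL, yval = NULL) {
  h <- spec$hyperparams$hidden
  nc <- nlevels(y)
  u <- if (nc == 2L) 1L else nc
  set.seed(spec$seed)
  layers <- list(layerDense(ncol(X), h[1L]), layerAct("sigmoidact"),
                 layerDense(h[1L], h[2L]), layerAct("sigmoidact"),
                 layerDense(h[2L], u))
  # zero-initialised output head: an untrained network predicts one
  # constant class, and training still receives nonzero head gradients
  layers[[5L]]$params$W[] <- 0
  fitDenseNet(layers, t(X), y, epochs = spec$hyperparams$epochs,
              batch = spec$hyperparams$batch, lr = spec$hyperparams$lr,
              Xval = if (is.null(Xval)) NULL else t(Xval), yval = yval)
}

#' Predict with a fitted baseline classifier
#'
#' @param model a fitted classifier from [fitBaseline()].
#' @param X feature matrix with the training column count.
#' @return factor of predicted labels (training label set).
#' @export
predictBaseline <- function(model, X) {
  stopifnot(inherits(model, "BaselineFit"))
  if (nrow(X) == 0L)
    return(factor(character(), levels = model$levels))
  if (ncol(X) != model$p)
    stop("feature width ", ncol(X), " does not match training width ",
         model$p)
  if (!is.null(model$center))
    X <- scale(X, center = model$center, scale = model$scale)
  switch(model$kind,
    knn = knnPredict(model$fit$X, model$fit$y, X, model$fit$k),
    rf = stats::predict(model$fit, X),
    fcn = {
      out <- denseNetLogits(model$fit$layers, t(X))
      factor(model$levels[logitsToClass(out)], levels = model$levels)
    })
}

# brute-force Euclidean KNN with the deterministic tie-break: ties in the
# vote go to the smallest label index; distance ties are resolved by row
# order (stable sort)
knnPredict <- function(Xtr, ytr, Xte, k) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), `+`) - 2 * Xte %*% t(Xtr)
  lev <- levels(ytr)
  idx <- apply(d2, 1L, function(row) order(row)[seq_len(k)])
  idx <- matrix(idx, nrow = k)
  pred <- apply(idx, 2L, function(nb) {
    votes <- tabulate(as.integer(ytr[nb]), nbins = length(lev))
    which.max(votes)           # first maximum = smallest label index
  })
  factor(lev[pred], levels = lev)
}

# ---- shared dense-network training utilities ---------------------------

sigmoidActForward <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = list(y = y))
}

denseForwardAll <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "sigmoidact") {
      r <- sigmoidActForward(X)
    } else r <- layerForward(l, X, training)
    caches[[i]] <- r$cache
    X <- r$y
  }
  list(out = X, caches = caches)
}

denseBackwardAll <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$kind == "sigmoidact") {
      y <- caches[[i]]$y
      dy <- dy * y * (1 - y)
      grads[[i]] <- list()
    } else {
      r <- layerBackward(l, caches[[i]], dy)
      grads[[i]] <- r$grads
      dy <- r$dx
    }
  }
  grads
}

denseNetLogits <- function(layers, X) denseForwardAll(layers, X)$out

logitsToClass <- function(out) {
  if (nrow(out) == 1L) as.integer(out[1L, ] > 0) + 1L
  else apply(out, 2L, which.max)
}

lossGrad <- function(out, yIdx, nClasses) {
  B <- ncol(out)
  if (nrow(out) == 1L) {
    p <- 1 / (1 + exp(-out))
    yv <- as.numeric(yIdx == 2L)
    loss <- -mean(yv * log(pmax(p, 1e-12)) +
                    (1 - yv) * log(pmax(1 - p, 1e-12)))
    list(loss = loss, d = (p - matrix(yv, 1L)) / B)
  } else {
    m <- apply(out, 2L, max)
    ex <- exp(sweep(out, 2L, m))
    P <- sweep(ex, 2L, colSums(ex), `/`)
    pick <- P[cbind(yIdx, seq_len(B))]
    loss <- -mean(log(pmax(pick, 1e-12)))
    Y <- matrix(0, nrow(out), B)
    Y[cbind(yIdx, seq_len(B))] <- 1
    list(loss = loss, d = (P - Y) / B)
  }
}

# Adam training of a plain dense stack on column-major data (features x n)
fitDenseNet <- function(layers, Xt, y, epochs, batch, lr,
                        Xval = NULL, yval = NULL) {
  yIdx <- as.integer(y)
  nc <- nlevels(y)
  state <- adamInit(layers)
  n <- ncol(Xt)
  best <- list(acc = -Inf, layers = layers)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b0 in seq(1L, n, by = batch)) {
      sel <- ord[b0:min(b0 + batch - 1L, n)]
      fw <- denseForwardAll(layers, Xt[, sel, drop = FALSE], training = TRUE)
      lg <- lossGrad(fw$out, yIdx[sel], nc)
      grads <- denseBackwardAll(layers, fw$caches, lg$d)
      step <- step + 1L
      upd <- adamStep(layers, grads, state, lr, step)
      layers <- upd$layers; state <- upd$state
    }
    if (!is.null(Xval) && length(yval)) {
      pv <- logitsToClass(denseNetLogits(layers, Xval))
      acc <- mean(pv == as.integer(factor(yval, levels = levels(y))))
      if (acc > best$acc) best <- list(acc = acc, layers = layers)
    }
  }
  if (is.finite(best$acc)) layers <- best$layers
  list(layers = layers, valAcc = if (is.finite(best$acc)) best$acc else NA)
}
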