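#' Training configuration
#'
#' @param lr Adam step size.
#' @param epochs training epochs (default 200).
#' @param batch minibatch size (default 100).
#' @param modelSelection `"best_val"` keeps the weights of the epoch with
#'   the highest validation accuracy; `"final"` keeps the last epoch.
#' @param seed integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return object of class `TrainConfig` (list).
#' @export
trainConfig <- function(lr = 1e-3, epochs = 200L, batch = 100L,
                        modelSelection = c("best_val", "final"), seed = 1L) {
  stopifnot(epochs >= 1L, batch >= 1L)
  structure(list(optimizer = "adam", lr = lr, epochs = as.integer(epochs),
                 batch = as.integer(batch),
                 modelSelection = match.arg(modelSelection),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' @export
print.TrainConfig <- function(x, ...) {
  cat(sprintf("TrainConfig: adam(lr %g), %d epochs, batch %d, selection %s, seed %d\n",
              x$lr, x$epochs, x$batch, x$modelSelection, x$seed))
  invisible(x)
}

# epochs array (n, C, T) -> engine tensor (1, T, C, n)
epochsToTensor <- function(ep) {
  d <- dim(ep)
  array(aperm(ep, c(3L, 2L, 1L)), dim = c(1L, d[3L], d[2L], d[1L]))
}

# per-channel standardisation statistics from a training tensor
channelStats <- function(x) {
  d <- dim(x)
  xm <- matrix(aperm(x[1L, , , , drop = FALSE], c(3L, 2L, 4L, 1L)), d[3L])
  m <- rowMeans(xm)
  s <- sqrt(rowMeans(xm^2) - m^2)
  s[s == 0 | !is.finite(s)] <- 1
  list(mean = m, sd = s)
}

applyChannelStats <- function(x, stats) {
  d <- dim(x)
  for (e in seq_len(d[3L]))
    x[, , e, ] <- (x[, , e, , drop = FALSE] - stats$mean[e]) / stats$sd[e]
  x
}

convNetPredict <- function(layers, x, batch = 256L) {
  n <- dim(x)[4L]
  out <- NULL
  for (b0 in seq(1L, n, by = batch)) {
    sel <- b0:min(b0 + batch - 1L, n)
    o <- nnForward(layers, x[, , , sel, drop = FALSE], training = FALSE)$out
    out <- if (is.null(out)) o else cbind(out, o)
  }
  out
}

#' Train a built ConvNet with Adam
#'
#' Minibatch Adam training with per-epoch loss logging and checkpoint
#' selection on validation accuracy.  Deterministic given the config seed
#' (which also reseeds weight initialisation through the model spec).
#'
#' @param net an [EEGConvNet-class].
#' @param x input tensor `(1, T, E, n)` (see [buildModel()] input layout).
#' @param yIdx integer class indices (1-based).
#' @param xval,yvalIdx validation tensor and class indices.
#' @param tc a [trainConfig()].
#' @return list with the trained `net`, `history` (per-epoch mean loss and
#'   validation accuracy) and `bestValAcc`.
#' @export
trainConvNet <- function(net, x, yIdx, xval = NULL, yvalIdx = NULL, tc) {
  stopifnot(is(net, "EEGConvNet"))
  layers <- net@layers
  nc <- net@spec@nClasses
  state <- adamInit(layers)
  n <- dim(x)[4L]
  set.seed(tc$seed)
  best <- list(acc = -Inf, layers = NULL)
  lossLog <- numeric(tc$epochs)
  valLog <- rep(NA_real_, tc$epochs)
  step <- 0L
  for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    epLoss <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = tc$batch)) {
      sel <- ord[b0:min(b0 + tc$batch - 1L, n)]
      fw <- nnForward(layers, x[, , , sel, drop = FALSE], training = TRUE)
      layers <- fw$layers
      lg <- lossGrad(fw$out, yIdx[sel], nc)
      grads <- nnBackward(layers, fw$caches, lg$d)
      step <- step + 1L
      upd <- adamStep(layers, grads, state, tc$lr, step)
      layers <- upd$layers; state <- upd$state
      epLoss <- epLoss + lg$loss; nb <- nb + 1L
    }
    lossLog[ep] <- epLoss / nb
    if (!is.null(xval) && length(yvalIdx)) {
      pv <- logitsToClass(convNetPredict(layers, xval))
      valLog[ep] <- mean(pv == yvalIdx)
      if (valLog[ep] > best$acc)
        best <- list(acc = valLog[ep], layers = layers)
    }
  }
  if (tc$modelSelection == "best_val" && !is.null(best$layers))
    layers <- best$layers
  net@layers <- layers
  list(net = net,
       history = list(loss = lossLog, valAccuracy = valLog),
       bestValAcc = if (is.finite(best$acc)) best$acc else NA_real_)
}

#' Predict classes with a trained ConvNet
#'
#' @param net a trained [EEGConvNet-class].
#' @param x input tensor `(1, T, E, n)`.
#' @return integer class indices (1-based).
#' @export
predictConvNet <- function(net, x) {
  logitsToClass(convNetPredict(net@layers, x))
}
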