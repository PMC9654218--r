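# Minimal feed-forward engine for EEG ConvNets.
#
# Feature tensors are arrays with dim (F, T, S, B): feature maps, time,
# space (electrodes; 1 after spatial collapse), batch.  Keeping the
# feature axis first makes per-feature broadcasting free in R (vector
# recycling runs along the first dimension) and lets convolutions reduce
# to BLAS matrix products via im2col.
#
# Raw EEG epochs enter as (1, T, E, B): one feature map, channels on the
# space axis.

glorot <- function(fanIn, fanOut, dims) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

sigmoidFn <- function(x) 1 / (1 + exp(-x))

poolOutLen <- function(t, len, stride = len) {
  if (t < len) stop("pooling exhausts the time axis (", t, " < ", len, ")")
  (t - len) %/% stride + 1L
}

# ---- temporal convolution core (im2col + gemm) -------------------------

padTime <- function(x, k) {
  d <- dim(x)
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  if (k == 1L) return(x)
  xp <- array(0, dim = c(d[1L], d[2L] + k - 1L, d[3L], d[4L]))
  xp[, (left + 1L):(left + d[2L]), , ] <- x
  xp
}

im2colTime <- function(xp, k, tOut) {
  d <- dim(xp)                       # (F, Tp, S, B)
  fin <- d[1L]
  cols <- d[3L] * d[4L] * tOut
  Xc <- matrix(0, k * fin, cols)
  for (dk in seq_len(k)) {
    block <- xp[, dk:(dk + tOut - 1L), , , drop = FALSE]
    Xc[((dk - 1L) * fin + 1L):(dk * fin), ] <- matrix(block, fin)
  }
  Xc
}

convTimeForward <- function(x, W, b, pad) {
  d <- dim(x)
  fin <- d[1L]; tIn <- d[2L]
  k <- ncol(W) / fin
  xp <- if (pad == "same") padTime(x, k) else x
  tOut <- if (pad == "same") tIn else tIn - k + 1L
  if (tOut < 1L) stop("temporal kernel longer than the input window")
  Xc <- im2colTime(xp, k, tOut)
  # Xc column order: (t, s, b) with t fastest -- matches array layout below
  Y <- W %*% Xc
  if (!is.null(b)) Y <- Y + b
  y <- array(Y, dim = c(nrow(W), tOut, d[3L], d[4L]))
  list(y = y, cache = list(Xc = Xc, dimIn = d, k = k, pad = pad, tOut = tOut))
}

convTimeBackward <- function(cache, W, dy) {
  d <- cache$dimIn
  fin <- d[1L]; k <- cache$k; tOut <- cache$tOut
  dyMat <- matrix(dy, nrow = dim(dy)[1L])
  dW <- dyMat %*% t(cache$Xc)
  db <- rowSums(dyMat)
  dXc <- crossprod(W, dyMat)
  tp <- if (cache$pad == "same") d[2L] + k - 1L else d[2L]
  dxp <- array(0, dim = c(fin, tp, d[3L], d[4L]))
  for (dk in seq_len(k)) {
    block <- array(dXc[((dk - 1L) * fin + 1L):(dk * fin), ],
                   dim = c(fin, tOut, d[3L], d[4L]))
    dxp[, dk:(dk + tOut - 1L), , ] <- dxp[, dk:(dk + tOut - 1L), , ,
                                          drop = FALSE] + block
  }
  if (cache$pad == "same") {
    left <- (k - 1L) %/% 2L
    dx <- dxp[, (left + 1L):(left + d[2L]), , , drop = FALSE]
  } else dx <- dxp
  list(dx = dx, dW = dW, db = db)
}

# ---- layer constructors ------------------------------------------------

layerTConv <- function(k, fin, fout, pad = "same", bias = TRUE) {
  list(kind = "tconv", k = k, fin = fin, fout = fout, pad = pad,
       bias = bias,
       params = list(W = glorot(k * fin, k * fout, c(fout, k * fin)),
                     b = if (bias) numeric(fout)))
}

layerBranchConv <- function(kernels, fin, m, pad = "same", bias = TRUE,
                            relu = TRUE, pool = 1L) {
  params <- list()
  for (j in seq_along(kernels)) {
    k <- kernels[j]
    params[[paste0("W", j)]] <- glorot(k * fin, k * m, c(m, k * fin))
    if (bias) params[[paste0("b", j)]] <- numeric(m)
  }
  list(kind = "branchconv", kernels = kernels, fin = fin, m = m, pad = pad,
       bias = bias, relu = relu, pool = as.integer(pool), params = params)
}

layerDWTConv <- function(k, fin, bias = FALSE) {
  list(kind = "dwtconv", k = k, fin = fin, bias = bias,
       params = list(W = glorot(k, k, c(fin, k)),
                     b = if (bias) numeric(fin)))
}

layerSpatialConv <- function(E, fin, fout, bias = TRUE) {
  list(kind = "spatialconv", E = E, fin = fin, fout = fout, bias = bias,
       params = list(W = glorot(E * fin, fout, c(fout, E * fin)),
                     b = if (bias) numeric(fout)))
}

layerSpatialDW <- function(E, fin, D, bias = TRUE) {
  list(kind = "spatialdw", E = E, fin = fin, D = D, bias = bias,
       params = list(W = glorot(E, D, c(E, fin, D)),
                     b = if (bias) numeric(fin * D)))
}

layerPWConv <- function(fin, fout, bias = TRUE) {
  list(kind = "pwconv", fin = fin, fout = fout, bias = bias,
       params = list(W = glorot(fin, fout, c(fin, fout)),
                     b = if (bias) numeric(fout)))
}

layerBatchNorm <- function(f, momentum = 0.1, eps = 1e-5) {
  list(kind = "batchnorm", f = f, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, f), beta = numeric(f)),
       runMean = numeric(f), runVar = rep(1, f))
}

layerSE <- function(f, r, bias = FALSE) {
  h <- max(1L, f %/% r)
  list(kind = "se", f = f, h = h, bias = bias,
       params = list(W1 = glorot(f, h, c(f, h)),
                     b1 = if (bias) numeric(h),
                     W2 = glorot(h, f, c(h, f)),
                     b2 = if (bias) numeric(f)))
}

layerAct <- function(kind) list(kind = kind, params = list())

layerPool <- function(kind, len, stride = len)
  list(kind = kind, len = as.integer(len), stride = as.integer(stride),
       params = list())

layerDropout <- function(rate) list(kind = "dropout", rate = rate,
                                    params = list())

layerFlatten <- function() list(kind = "flatten", params = list())

layerDense <- function(fin, fout, bias = TRUE) {
  list(kind = "dense", fin = fin, fout = fout, bias = bias,
       params = list(W = glorot(fin, fout, c(fin, fout)),
                     b = if (bias) numeric(fout)))
}

# ---- forward / backward ------------------------------------------------

layerForward <- function(layer, x, training) {
  switch(layer$kind,
    tconv = {
      r <- convTimeForward(x, layer$params$W, layer$params$b, layer$pad)
      list(y = r$y, cache = r$cache)
    },
    branchconv = {
      outs <- list(); caches <- list()
      for (j in seq_along(layer$kernels)) {
        r <- convTimeForward(x, layer$params[[paste0("W", j)]],
                             layer$params[[paste0("b", j)]], layer$pad)
        y <- r$y
        cj <- list(conv = r$cache)
        if (layer$relu) { cj$pre <- y; y <- pmax(y, 0) }
        if (layer$pool > 1L) {
          p <- poolForward(y, "avgpool", layer$pool, layer$pool)
          cj$pool <- p$cache
          y <- p$y
        }
        outs[[j]] <- y; caches[[j]] <- cj
      }
      d1 <- dim(outs[[1L]])
      y <- array(0, dim = c(layer$m * length(outs), d1[2L], d1[3L], d1[4L]))
      for (j in seq_along(outs))
        y[((j - 1L) * layer$m + 1L):(j * layer$m), , , ] <- outs[[j]]
      list(y = y, cache = caches)
    },
    dwtconv = {
      d <- dim(x)
      k <- layer$k
      xp <- padTime(x, k)
      W <- layer$params$W
      y <- array(0, dim = d)
      for (dk in seq_len(k))
        y <- y + xp[, dk:(dk + d[2L] - 1L), , , drop = FALSE] * W[, dk]
      if (layer$bias) y <- y + layer$params$b
      list(y = y, cache = list(xp = xp, dimIn = d))
    },
    spatialconv = {
      d <- dim(x)                          # (F, T, E, B)
      Xm <- matrix(aperm(x, c(1L, 3L, 2L, 4L)), d[1L] * d[3L])
      Y <- layer$params$W %*% Xm
      if (layer$bias) Y <- Y + layer$params$b
      list(y = array(Y, dim = c(layer$fout, d[2L], 1L, d[4L])),
           cache = list(Xm = Xm, dimIn = d))
    },
    spatialdw = {
      d <- dim(x)
      D <- layer$D
      y <- array(0, dim = c(d[1L] * D, d[2L], 1L, d[4L]))
      Xfs <- vector("list", d[1L])
      for (f in seq_len(d[1L])) {
        xf <- array(x[f, , , ], dim = d[2:4])          # (T, E, B)
        Xf <- matrix(aperm(xf, c(1L, 3L, 2L)), d[2L] * d[4L])  # (T*B, E)
        Yf <- Xf %*% layer$params$W[, f, ]             # (T*B, D)
        y[((f - 1L) * D + 1L):(f * D), , 1L, ] <- t(Yf)
        Xfs[[f]] <- Xf
      }
      if (layer$bias) y <- y + layer$params$b
      list(y = y, cache = list(Xfs = Xfs, dimIn = d))
    },
    pwconv = {
      d <- dim(x)
      Xm <- matrix(x, d[1L])
      Y <- crossprod(layer$params$W, Xm)
      if (layer$bias) Y <- Y + layer$params$b
      list(y = array(Y, dim = c(layer$fout, d[2L], d[3L], d[4L])),
           cache = list(Xm = Xm, dimIn = d))
    },
    batchnorm = {
      d <- dim(x); f <- d[1L]
      if (training) {
        Xm <- matrix(x, f)
        m <- rowMeans(Xm)
        v <- rowMeans(Xm^2) - m^2
        layer$runMean <- (1 - layer$momentum) * layer$runMean + layer$momentum * m
        layer$runVar <- (1 - layer$momentum) * layer$runVar + layer$momentum * v
      } else { m <- layer$runMean; v <- layer$runVar }
      ivar <- 1 / sqrt(v + layer$eps)
      xhat <- (x - m) * ivar
      y <- layer$params$gamma * xhat + layer$params$beta
      list(y = y, cache = list(xhat = xhat, ivar = ivar, training = training),
           layer = layer)
    },
    se = {
      d <- dim(x); f <- d[1L]; ts <- d[2L] * d[3L]
      s <- colMeans(aperm(array(x, c(f, ts, d[4L])), c(2L, 1L, 3L)))  # (F,B)
      s <- matrix(s, f)
      pre1 <- crossprod(layer$params$W1, s)
      if (layer$bias) pre1 <- pre1 + layer$params$b1
      z1 <- pmax(pre1, 0)
      pre2 <- crossprod(layer$params$W2, z1)
      if (layer$bias) pre2 <- pre2 + layer$params$b2
      g <- sigmoidFn(pre2)                               # (F,B)
      garr <- aperm(array(g, c(f, d[4L], ts)), c(1L, 3L, 2L))
      dim(garr) <- d
      list(y = x * garr,
           cache = list(x = x, s = s, pre1 = pre1, z1 = z1, g = g,
                        garr = garr, dimIn = d))
    },
    relu = list(y = pmax(x, 0), cache = list(x = x)),
    elu = {
      y <- ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
      list(y = y, cache = list(x = x, y = y))
    },
    square = list(y = x * x, cache = list(x = x)),
    logeps = {
      xc <- pmax(x, 1e-6)
      list(y = log(xc), cache = list(xc = xc))
    },
    avgpool = poolForward(x, "avgpool", layer$len, layer$stride),
    maxpool = poolForward(x, "maxpool", layer$len, layer$stride),
    dropout = {
      if (training && layer$rate > 0) {
        mask <- array(stats::runif(length(x)) >= layer$rate, dim = dim(x))
        list(y = x * mask / (1 - layer$rate), cache = list(mask = mask))
      } else list(y = x, cache = list(mask = NULL))
    },
    flatten = {
      d <- dim(x)
      list(y = matrix(x, d[1L] * d[2L] * d[3L], d[4L]),
           cache = list(dimIn = d))
    },
    dense = {
      Y <- crossprod(layer$params$W, x)
      if (layer$bias) Y <- Y + layer$params$b
      list(y = Y, cache = list(x = x))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

poolForward <- function(x, kind, len, stride) {
  d <- dim(x)
  tOut <- poolOutLen(d[2L], len, stride)
  pos <- function(dk) dk + (0:(tOut - 1L)) * stride
  if (kind == "avgpool") {
    y <- array(0, dim = c(d[1L], tOut, d[3L], d[4L]))
    for (dk in seq_len(len))
      y <- y + x[, pos(dk), , , drop = FALSE]
    y <- y / len
    list(y = y, cache = list(dimIn = d, len = len, stride = stride,
                             tOut = tOut))
  } else {
    y <- array(-Inf, dim = c(d[1L], tOut, d[3L], d[4L]))
    arg <- array(0L, dim = dim(y))
    for (dk in seq_len(len)) {
      slice <- x[, pos(dk), , , drop = FALSE]
      upd <- slice > y
      y[upd] <- slice[upd]
      arg[upd] <- dk
    }
    list(y = y, cache = list(dimIn = d, len = len, stride = stride,
                             tOut = tOut, arg = arg))
  }
}

poolBackward <- function(cache, kind, dy) {
  d <- cache$dimIn
  dx <- array(0, dim = d)
  pos <- function(dk) dk + (0:(cache$tOut - 1L)) * cache$stride
  for (dk in seq_len(cache$len)) {
    contrib <- if (kind == "avgpool") dy / cache$len
               else dy * (cache$arg == dk)
    p <- pos(dk)
    dx[, p, , ] <- dx[, p, , , drop = FALSE] + contrib
  }
  dx
}

layerBackward <- function(layer, cache, dy) {
  switch(layer$kind,
    tconv = {
      r <- convTimeBackward(cache, layer$params$W, dy)
      g <- list(W = r$dW)
      if (layer$bias) g$b <- r$db
      list(dx = r$dx, grads = g)
    },
    branchconv = {
      m <- layer$m
      grads <- list()
      dx <- NULL
      for (j in seq_along(layer$kernels)) {
        dyj <- dy[((j - 1L) * m + 1L):(j * m), , , , drop = FALSE]
        cj <- cache[[j]]
        if (layer$pool > 1L) dyj <- poolBackward(cj$pool, "avgpool", dyj)
        if (layer$relu) dyj <- dyj * (cj$pre > 0)
        r <- convTimeBackward(cj$conv, layer$params[[paste0("W", j)]], dyj)
        grads[[paste0("W", j)]] <- r$dW
        if (layer$bias) grads[[paste0("b", j)]] <- r$db
        dx <- if (is.null(dx)) r$dx else dx + r$dx
      }
      list(dx = dx, grads = grads)
    },
    dwtconv = {
      d <- cache$dimIn
      k <- layer$k
      W <- layer$params$W
      dW <- matrix(0, d[1L], k)
      dxp <- array(0, dim = dim(cache$xp))
      for (dk in seq_len(k)) {
        sl <- cache$xp[, dk:(dk + d[2L] - 1L), , , drop = FALSE]
        dW[, dk] <- rowSums(matrix(sl * dy, d[1L]))
        dxp[, dk:(dk + d[2L] - 1L), , ] <-
          dxp[, dk:(dk + d[2L] - 1L), , , drop = FALSE] + dy * W[, dk]
      }
      left <- (k - 1L) %/% 2L
      dx <- dxp[, (left + 1L):(left + d[2L]), , , drop = FALSE]
      g <- list(W = dW)
      if (layer$bias) g$b <- rowSums(matrix(dy, d[1L]))
      list(dx = dx, grads = g)
    },
    spatialconv = {
      d <- cache$dimIn
      dyMat <- matrix(dy, layer$fout)
      dW <- dyMat %*% t(cache$Xm)
      dXm <- crossprod(layer$params$W, dyMat)
      dx <- aperm(array(dXm, dim = c(d[1L], d[3L], d[2L], d[4L])),
                  c(1L, 3L, 2L, 4L))
      g <- list(W = dW)
      if (layer$bias) g$b <- rowSums(dyMat)
      list(dx = dx, grads = g)
    },
    spatialdw = {
      d <- cache$dimIn
      D <- layer$D
      dW <- array(0, dim = dim(layer$params$W))
      dx <- array(0, dim = d)
      for (f in seq_len(d[1L])) {
        dyf <- matrix(dy[((f - 1L) * D + 1L):(f * D), , 1L, ], D)  # (D, T*B)
        Xf <- cache$Xfs[[f]]
        dW[, f, ] <- crossprod(Xf, t(dyf))
        dXf <- t(dyf) %*% t(matrix(layer$params$W[, f, ], ncol = D))
        dx[f, , , ] <- aperm(array(dXf, dim = c(d[2L], d[4L], d[3L])),
                             c(1L, 3L, 2L))
      }
      g <- list(W = dW)
      if (layer$bias) g$b <- rowSums(matrix(dy, d[1L] * D))
      list(dx = dx, grads = g)
    },
    pwconv = {
      d <- cache$dimIn
      dyMat <- matrix(dy, layer$fout)
      dW <- cache$Xm %*% t(dyMat)
      dXm <- layer$params$W %*% dyMat
      g <- list(W = dW)
      if (layer$bias) g$b <- rowSums(dyMat)
      list(dx = array(dXm, dim = d), grads = g)
    },
    batchnorm = {
      f <- layer$f
      xhat <- cache$xhat
      n <- length(xhat) / f
      dgamma <- rowSums(matrix(dy * xhat, f))
      dbeta <- rowSums(matrix(dy, f))
      dxhat <- dy * layer$params$gamma
      if (cache$training) {
        s1 <- rowSums(matrix(dxhat, f))
        s2 <- rowSums(matrix(dxhat * xhat, f))
        dx <- (cache$ivar / n) * (n * dxhat - s1 - xhat * s2)
      } else dx <- dxhat * cache$ivar
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    se = {
      d <- cache$dimIn; f <- d[1L]; ts <- d[2L] * d[3L]
      g <- cache$g
      dgate <- colSums(aperm(array(dy * cache$x, c(f, ts, d[4L])),
                             c(2L, 1L, 3L)))
      dgate <- matrix(dgate, f)
      dpre2 <- dgate * g * (1 - g)
      dW2 <- cache$z1 %*% t(dpre2)
      dz1 <- layer$params$W2 %*% dpre2
      dpre1 <- dz1 * (cache$pre1 > 0)
      dW1 <- cache$s %*% t(dpre1)
      ds <- layer$params$W1 %*% dpre1                 # (F, B)
      dsarr <- aperm(array(ds, c(f, d[4L], ts)), c(1L, 3L, 2L))
      dim(dsarr) <- d
      dx <- dy * cache$garr + dsarr / ts
      grads <- list(W1 = dW1, W2 = dW2)
      if (layer$bias) {
        grads$b1 <- rowSums(dpre1)
        grads$b2 <- rowSums(dpre2)
      }
      list(dx = dx, grads = grads)
    },
    relu = list(dx = dy * (cache$x > 0), grads = list()),
    elu = list(dx = dy * ifelse(cache$x > 0, 1, cache$y + 1), grads = list()),
    square = list(dx = 2 * cache$x * dy, grads = list()),
    logeps = list(dx = dy / cache$xc, grads = list()),
    avgpool = list(dx = poolBackward(cache, "avgpool", dy), grads = list()),
    maxpool = list(dx = poolBackward(cache, "maxpool", dy), grads = list()),
    dropout = {
      dx <- if (is.null(cache$mask)) dy else dy * cache$mask / (1 - layer$rate)
      list(dx = dx, grads = list())
    },
    flatten = list(dx = array(dy, dim = cache$dimIn), grads = list()),
    dense = {
      dW <- cache$x %*% t(dy)
      dx <- layer$params$W %*% dy
      g <- list(W = dW)
      if (layer$bias) g$b <- rowSums(dy)
      list(dx = dx, grads = g)
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

nnForward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layerForward(layers[[i]], x, training)
    if (!is.null(r$layer)) layers[[i]] <- r$layer   # BN running stats
    caches[[i]] <- r$cache
    x <- r$y
  }
  list(out = x, caches = caches, layers = layers)
}

nnBackward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  dy <- dout
  for (i in rev(seq_along(layers))) {
    r <- layerBackward(layers[[i]], caches[[i]], dy)
    grads[[i]] <- r$grads
    dy <- r$dx
  }
  grads
}

# ---- Adam --------------------------------------------------------------

adamInit <- function(layers) {
  lapply(layers, function(l)
    lapply(l$params, function(p)
      if (is.null(p)) NULL else list(m = p * 0, v = p * 0)))
}

adamStep <- function(layers, grads, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      p <- layers[[i]]$params[[nm]]
      g <- grads[[i]][[nm]]
      if (is.null(p) || is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- p - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

countLayerParams <- function(layers) {
  sum(vapply(layers, function(l)
    sum(vapply(l$params, function(p)
      if (is.null(p)) 0L else length(p), integer(1))), integer(1)))
}
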