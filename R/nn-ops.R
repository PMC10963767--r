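## Low-level numeric operations for the fusion network.
##
## Batched feature maps are numeric arrays of dim c(H, W, C, N); dense
## activations are matrices of dim c(F, N) (one column per sample). Every
## forward returns list(y, cache); every backward takes (cache, dy) and
## returns list(dx, <parameter gradients>). Gradients are exact (verified by
## finite differences in the test suite). Convolutions use im2col so the
## heavy lifting is a single BLAS matrix product.

## --- padding ---------------------------------------------------------------

padHW <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  out
}

cropHW <- function(x, p, H, W) {
  if (p == 0L) return(x)
  x[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE]
}

convOutLen <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

## --- convolution (im2col) --------------------------------------------------

## W: array(kh, kw, Cin, Cout); b: numeric(Cout).
## pad = "same" resolves to (k-1)/2 for odd kernels at stride 1.
## Implemented as shift-and-matmul: the padded input is permuted once to
## (H, W, N, C) so every kernel offset contributes one BLAS product.
nnConvForward <- function(x, W, b, stride = 1L, pad = "same") {
  d <- dim(x)
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  wfAssert(d[3] == Cin, "conv: input has ", d[3], " channels, kernel expects ", Cin)
  if (identical(pad, "same")) pad <- (kh - 1L) %/% 2L
  pad <- as.integer(pad); stride <- as.integer(stride)
  Ho <- convOutLen(d[1], kh, stride, pad)
  Wo <- convOutLen(d[2], kw, stride, pad)
  N <- d[4]
  xb <- aperm(padHW(x, pad), c(1, 2, 4, 3))      # (Hp, Wp, N, Cin)
  M <- matrix(0, Ho * Wo * N, Cout)
  for (di in seq_len(kh)) {
    ri <- seq.int(di, by = stride, length.out = Ho)
    for (dj in seq_len(kw)) {
      cj <- seq.int(dj, by = stride, length.out = Wo)
      sl <- xb[ri, cj, , , drop = FALSE]
      dim(sl) <- c(Ho * Wo * N, Cin)
      M <- M + sl %*% matrix(W[di, dj, , ], Cin, Cout)
    }
  }
  M <- M + rep(b, each = Ho * Wo * N)
  y <- aperm(array(M, c(Ho, Wo, N, Cout)), c(1, 2, 4, 3))
  list(y = y,
       cache = list(xb = xb, Wdim = dim(W), inDim = d, stride = stride,
                    pad = pad, Ho = Ho, Wo = Wo, W = W))
}

nnConvBackward <- function(cache, dy) {
  kd <- cache$Wdim; d <- cache$inDim
  kh <- kd[1]; kw <- kd[2]; Cin <- kd[3]; Cout <- kd[4]
  Ho <- cache$Ho; Wo <- cache$Wo; N <- d[4]
  dyMat <- matrix(aperm(dy, c(1, 2, 4, 3)), Ho * Wo * N, Cout)
  dW <- array(0, kd)
  dXb <- array(0, dim(cache$xb))
  for (di in seq_len(kh)) {
    ri <- seq.int(di, by = cache$stride, length.out = Ho)
    for (dj in seq_len(kw)) {
      cj <- seq.int(dj, by = cache$stride, length.out = Wo)
      sl <- cache$xb[ri, cj, , , drop = FALSE]
      dim(sl) <- c(Ho * Wo * N, Cin)
      dW[di, dj, , ] <- crossprod(sl, dyMat)
      dsl <- tcrossprod(dyMat, matrix(cache$W[di, dj, , ], Cin, Cout))
      dim(dsl) <- c(Ho, Wo, N, Cin)
      dXb[ri, cj, , ] <- dXb[ri, cj, , , drop = FALSE] + dsl
    }
  }
  db <- colSums(dyMat)
  dx <- cropHW(aperm(dXb, c(1, 2, 4, 3)), cache$pad, d[1], d[2])
  list(dx = dx, dW = dW, db = db)
}

## --- depthwise convolution (EfficientNet) ----------------------------------

## Wd: array(kh, kw, C); per-channel spatial filter.
nnDepthwiseForward <- function(x, Wd, b, stride = 1L, pad = "same") {
  d <- dim(x); kh <- dim(Wd)[1]; kw <- dim(Wd)[2]; C <- dim(Wd)[3]
  wfAssert(d[3] == C, "depthwise conv: channel mismatch")
  if (identical(pad, "same")) pad <- (kh - 1L) %/% 2L
  pad <- as.integer(pad); stride <- as.integer(stride)
  Ho <- convOutLen(d[1], kh, stride, pad)
  Wo <- convOutLen(d[2], kw, stride, pad)
  N <- d[4]
  Xp <- padHW(x, pad)
  y <- array(rep(b, each = Ho * Wo), c(Ho, Wo, C, N))
  for (di in seq_len(kh)) {
    ri <- seq.int(di, by = stride, length.out = Ho)
    for (dj in seq_len(kw)) {
      cj <- seq.int(dj, by = stride, length.out = Wo)
      y <- y + Xp[ri, cj, , , drop = FALSE] *
        rep(rep(Wd[di, dj, ], each = Ho * Wo), times = N)
    }
  }
  list(y = y, cache = list(Xp = Xp, Wd = Wd, inDim = d, stride = stride,
                           pad = pad, Ho = Ho, Wo = Wo))
}

nnDepthwiseBackward <- function(cache, dy) {
  d <- cache$inDim; Wd <- cache$Wd
  kh <- dim(Wd)[1]; kw <- dim(Wd)[2]; C <- dim(Wd)[3]
  Ho <- cache$Ho; Wo <- cache$Wo; N <- d[4]
  dWd <- array(0, dim(Wd))
  dXp <- array(0, dim(cache$Xp))
  for (di in seq_len(kh)) {
    ri <- seq.int(di, by = cache$stride, length.out = Ho)
    for (dj in seq_len(kw)) {
      cj <- seq.int(dj, by = cache$stride, length.out = Wo)
      patch <- cache$Xp[ri, cj, , , drop = FALSE]
      pr <- colSums(matrix(patch * dy, Ho * Wo, C * N))
      dWd[di, dj, ] <- rowSums(matrix(pr, C, N))
      dXp[ri, cj, , ] <- dXp[ri, cj, , , drop = FALSE] +
        dy * rep(rep(Wd[di, dj, ], each = Ho * Wo), times = N)
    }
  }
  db <- rowSums(matrix(colSums(matrix(dy, Ho * Wo, C * N)), C, N))
  list(dx = cropHW(dXp, cache$pad, d[1], d[2]), dW = dWd, db = db)
}

## --- pooling ---------------------------------------------------------------

nnMaxPoolForward <- function(x, k = 2L, stride = k, pad = 0L) {
  d <- dim(x); k <- as.integer(k); stride <- as.integer(stride); pad <- as.integer(pad)
  Ho <- convOutLen(d[1], k, stride, pad)
  Wo <- convOutLen(d[2], k, stride, pad)
  C <- d[3]; N <- d[4]
  Xp <- if (pad > 0L) {
    tmp <- array(-Inf, c(d[1] + 2L * pad, d[2] + 2L * pad, C, N))
    tmp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), , ] <- x
    tmp
  } else x
  kk <- k * k
  cols <- array(0, c(Ho, Wo, C, N, kk))
  s <- 0L
  for (di in seq_len(k)) {
    ri <- seq.int(di, by = stride, length.out = Ho)
    for (dj in seq_len(k)) {
      cj <- seq.int(dj, by = stride, length.out = Wo)
      s <- s + 1L
      cols[, , , , s] <- Xp[ri, cj, , ]
    }
  }
  m <- matrix(cols, Ho * Wo * C * N, kk)
  amax <- max.col(m, ties.method = "first")
  y <- array(m[cbind(seq_len(nrow(m)), amax)], c(Ho, Wo, C, N))
  list(y = y, cache = list(amax = amax, k = k, stride = stride, pad = pad,
                           inDim = d, Ho = Ho, Wo = Wo))
}

nnMaxPoolBackward <- function(cache, dy) {
  d <- cache$inDim; k <- cache$k; Ho <- cache$Ho; Wo <- cache$Wo
  C <- d[3]; N <- d[4]; pad <- cache$pad
  dXp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, C, N))
  ## recover (di, dj) from flat window slot
  slotDi <- ((cache$amax - 1L) %/% k) + 1L
  slotDj <- ((cache$amax - 1L) %% k) + 1L
  idx <- arrayInd(seq_len(Ho * Wo * C * N), c(Ho, Wo, C, N))
  rows <- (idx[, 1] - 1L) * cache$stride + slotDi
  colsj <- (idx[, 2] - 1L) * cache$stride + slotDj
  flat <- cbind(rows, colsj, idx[, 3], idx[, 4])
  lin <- (flat[, 4] - 1L)
  dimsP <- dim(dXp)
  linIdx <- flat[, 1] + dimsP[1] * (flat[, 2] - 1L) +
    dimsP[1] * dimsP[2] * (flat[, 3] - 1L) +
    dimsP[1] * dimsP[2] * dimsP[3] * lin
  gy <- as.vector(dy)
  agg <- rowsum(gy, linIdx)
  dXp[as.integer(rownames(agg))] <- dXp[as.integer(rownames(agg))] + agg[, 1]
  list(dx = cropHW(dXp, pad, d[1], d[2]))
}

nnAvgPoolForward <- function(x, k = 2L) {
  d <- dim(x); k <- as.integer(k)
  wfAssert(d[1] %% k == 0L && d[2] %% k == 0L, "avgpool: size not divisible")
  Ho <- d[1] %/% k; Wo <- d[2] %/% k
  y <- array(0, c(Ho, Wo, d[3], d[4]))
  for (di in seq_len(k)) {
    ri <- seq.int(di, by = k, length.out = Ho)
    for (dj in seq_len(k)) {
      cj <- seq.int(dj, by = k, length.out = Wo)
      y <- y + x[ri, cj, , , drop = FALSE]
    }
  }
  list(y = y / (k * k), cache = list(k = k, inDim = d))
}

nnAvgPoolBackward <- function(cache, dy) {
  k <- cache$k; d <- cache$inDim
  dx <- array(0, d)
  g <- dy / (k * k)
  for (di in seq_len(k)) {
    ri <- seq.int(di, by = k, length.out = d[1] %/% k)
    for (dj in seq_len(k)) {
      cj <- seq.int(dj, by = k, length.out = d[2] %/% k)
      dx[ri, cj, , ] <- g
    }
  }
  list(dx = dx)
}

## Adaptive average pooling to a fixed (oh, ow) grid (PyTorch bin rule).
adaptiveBins <- function(n, o) {
  lapply(seq_len(o), function(i) {
    s <- floor((i - 1) * n / o) + 1L
    e <- ceiling(i * n / o)
    s:e
  })
}

nnAdaptiveAvgPoolForward <- function(x, oh, ow) {
  d <- dim(x)
  if (d[1] == oh && d[2] == ow)
    return(list(y = x, cache = list(identity = TRUE, inDim = d)))
  rb <- adaptiveBins(d[1], oh); cb <- adaptiveBins(d[2], ow)
  y <- array(0, c(oh, ow, d[3], d[4]))
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    sl <- x[rb[[i]], cb[[j]], , , drop = FALSE]
    y[i, j, , ] <- colMeans(matrix(sl, length(rb[[i]]) * length(cb[[j]]),
                                   d[3] * d[4]))
  }
  list(y = y, cache = list(identity = FALSE, rb = rb, cb = cb, inDim = d,
                           oh = oh, ow = ow))
}

nnAdaptiveAvgPoolBackward <- function(cache, dy) {
  if (isTRUE(cache$identity)) return(list(dx = dy))
  d <- cache$inDim
  dx <- array(0, d)
  for (i in seq_len(cache$oh)) for (j in seq_len(cache$ow)) {
    nr <- length(cache$rb[[i]]); nc <- length(cache$cb[[j]])
    g <- dy[i, j, , , drop = FALSE] / (nr * nc)
    dx[cache$rb[[i]], cache$cb[[j]], , ] <-
      dx[cache$rb[[i]], cache$cb[[j]], , , drop = FALSE] +
      array(rep(as.vector(g), each = nr * nc), c(nr, nc, d[3], d[4]))
  }
  list(dx = dx)
}

## --- pointwise nonlinearities ---------------------------------------------

nnReluForward <- function(x) list(y = pmax(x, 0), cache = list(mask = x > 0))
nnReluBackward <- function(cache, dy) list(dx = dy * cache$mask)

nnSigmoid <- function(x) 1 / (1 + exp(-x))

nnSwishForward <- function(x) {
  s <- nnSigmoid(x)
  list(y = x * s, cache = list(x = x, s = s))
}
nnSwishBackward <- function(cache, dy) {
  s <- cache$s
  list(dx = dy * (s + cache$x * s * (1 - s)))
}

## --- batch normalisation ---------------------------------------------------

## Per-channel over (H, W, N). Batch statistics are used during training,
## running statistics during inference.
nnBatchNormForward <- function(x, gamma, beta, running, training,
                               eps = 1e-5, momentum = 0.1) {
  d <- dim(x); C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean; v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, invstd, "*")
  ym <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = y, running = running,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d,
                    training = training))
}

nnBatchNormBackward <- function(cache, dy) {
  d <- cache$d; C <- d[3]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), d[1] * d[2] * d[4], C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  m <- nrow(dym)
  if (cache$training) {
    t1 <- sweep(dym, 2, colMeans(dym), "-")
    t2 <- sweep(cache$xhat, 2, colMeans(dym * cache$xhat), "*")
    dxhat <- t1 - t2
  } else {
    dxhat <- dym
  }
  dxm <- sweep(dxhat, 2, cache$gamma * cache$invstd, "*")
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## --- dense -----------------------------------------------------------------

## x: (F, N); W: (out, F); b: numeric(out).
nnDenseForward <- function(x, W, b) {
  list(y = W %*% x + b, cache = list(x = x, W = W))
}
nnDenseBackward <- function(cache, dy) {
  list(dx = crossprod(cache$W, dy),
       dW = dy %*% t(cache$x),
       db = rowSums(dy))
}

## --- dropout ---------------------------------------------------------------

nnDropoutForward <- function(x, rate, training) {
  if (!training || rate <= 0)
    return(list(y = x, cache = list(mask = NULL)))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x) %||% length(x))
  list(y = x * mask, cache = list(mask = mask))
}
nnDropoutBackward <- function(cache, dy) {
  if (is.null(cache$mask)) return(list(dx = dy))
  list(dx = dy * cache$mask)
}

## --- softmax / cross-entropy ----------------------------------------------

## logits: (K, N). Returns probabilities column-wise.
nnSoftmax <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

## y: integer labels in 1..K. Returns mean loss and dlogits (already /N).
nnSoftmaxCrossEntropy <- function(logits, y, eps = 1e-12) {
  p <- nnSoftmax(logits)
  N <- ncol(logits)
  picked <- p[cbind(y, seq_len(N))]
  loss <- mean(-log(pmax(picked, eps)))
  dlogits <- p
  dlogits[cbind(y, seq_len(N))] <- dlogits[cbind(y, seq_len(N))] - 1
  list(loss = loss, p = p, dlogits = dlogits / N)
}
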