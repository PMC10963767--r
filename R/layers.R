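## Generic layer engine: backbones and the aggregation / head stacks are
## lists of layer descriptors. Each descriptor carries its type, its
## parameters (numeric arrays) and static settings. layerForward /
## layerBackward dispatch on type; seqForward / seqBackward chain a stack.
## Parameter trees (nested lists of arrays) extracted by seqParams align
## exactly with the gradient trees returned by seqBackward, which is what
## the Adam optimizer walks.

mkConv <- function(inC, outC, k = 3L, stride = 1L, pad = "same") {
  list(type = "conv",
       params = list(W = heInit(c(k, k, inC, outC), k * k * inC),
                     b = numeric(outC)),
       stride = as.integer(stride), pad = pad, inC = inC, outC = outC, k = k)
}

mkDwConv <- function(C, k = 3L, stride = 1L) {
  list(type = "dwconv",
       params = list(W = heInit(c(k, k, C), k * k), b = numeric(C)),
       stride = as.integer(stride), inC = C, outC = C, k = k)
}

mkBN <- function(C) {
  list(type = "bn", params = list(gamma = rep(1, C), beta = numeric(C)),
       running = list(mean = numeric(C), var = rep(1, C)), inC = C, outC = C)
}

mkRelu <- function() list(type = "relu", params = list())
mkSwish <- function() list(type = "swish", params = list())
mkMaxPool <- function(k = 2L, stride = k, pad = 0L)
  list(type = "maxpool", params = list(), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
mkAvgPool <- function(k = 2L)
  list(type = "avgpool", params = list(), k = as.integer(k))
mkAdapt <- function(oh, ow)
  list(type = "adaptpool", params = list(), oh = as.integer(oh),
       ow = as.integer(ow))
mkDropout <- function(rate)
  list(type = "dropout", params = list(), rate = rate)
mkFlatten <- function() list(type = "flatten", params = list())

mkDense <- function(inF, outF) {
  list(type = "dense",
       params = list(W = heInit(c(outF, inF), inF), b = numeric(outF)),
       inF = inF, outF = outF)
}

mkPscse <- function(C, r = 16L, merge = "maxout_add") {
  list(type = "pscse",
       params = list(
         ## small positive excitation bias avoids a dead ReLU bottleneck
         ## at initialisation
         cse = list(W1 = heInit(c(max(1L, ceiling(C / r)), C), C),
                    b1 = rep(0.01, max(1L, ceiling(C / r))),
                    W2 = heInit(c(C, max(1L, ceiling(C / r))),
                                max(1L, ceiling(C / r))),
                    b2 = numeric(C)),
         sse = list(w = as.vector(heInit(C, C)), b = 0)),
       merge = merge, inC = C, outC = C)
}

## Layer normalisation over the feature dimension of a (F, N) matrix; the
## standard companion of residual attention, keeping the attention inputs
## on a stable scale.
mkLN <- function(f) {
  list(type = "ln", params = list(gamma = rep(1, f), beta = numeric(f)),
       f = f)
}

nnLayerNormForward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xh <- sweep(xc, 2, inv, "*")
  list(y = xh * gamma + beta, cache = list(xh = xh, inv = inv, gamma = gamma))
}

nnLayerNormBackward <- function(cache, dy) {
  dgamma <- rowSums(dy * cache$xh)
  dbeta <- rowSums(dy)
  dxh <- dy * cache$gamma
  t1 <- sweep(dxh, 2, colMeans(dxh), "-")
  t2 <- sweep(cache$xh, 2, colMeans(dxh * cache$xh), "*")
  list(dx = sweep(t1 - t2, 2, cache$inv, "*"), dgamma = dgamma,
       dbeta = dbeta)
}

mkVattn <- function(f) {
  s <- vattnGridSide(f)
  sc <- sqrt(6 / (2 * s))
  mkW <- function() array(stats::runif(s * s, -sc, sc), c(s, s))
  list(type = "vattn",
       params = list(p1 = list(Wq = mkW(), Wk = mkW(), Wv = mkW()),
                     p2 = list(Wq = mkW(), Wk = mkW(), Wv = mkW())),
       f = f)
}

## EfficientNet-style squeeze-and-excitation (swish bottleneck).
mkSE <- function(C, reduced) {
  list(type = "se",
       params = list(W1 = heInit(c(reduced, C), C), b1 = numeric(reduced),
                     W2 = heInit(c(C, reduced), reduced), b2 = numeric(C)),
       inC = C, outC = C)
}

## Residual block: y = act(main(x) + down(x)); down NULL means identity.
mkRes <- function(main, down = NULL, finalRelu = TRUE) {
  list(type = "res", params = list(), main = main, down = down,
       finalRelu = finalRelu)
}

## --- SE forward/backward (swish variant of cSE) ----------------------------

wfSeFwd <- function(x, p) {
  d <- dim(x); HW <- d[1] * d[2]
  z <- matrix(colMeans(matrix(x, HW, d[3] * d[4])), d[3], d[4])
  h1 <- p$W1 %*% z + p$b1
  hs <- nnSwishForward(h1)
  s <- nnSigmoid(p$W2 %*% hs$y + p$b2)
  sb <- array(rep(as.vector(s), each = HW), d)
  list(y = x * sb, cache = list(x = x, z = z, hs = hs, s = s, sb = sb, d = d))
}

wfSeBwd <- function(cache, dy, p) {
  d <- cache$d; HW <- d[1] * d[2]
  ds <- matrix(colSums(matrix(dy * cache$x, HW, d[3] * d[4])), d[3], d[4])
  dpre2 <- ds * cache$s * (1 - cache$s)
  dW2 <- dpre2 %*% t(cache$hs$y)
  db2 <- rowSums(dpre2)
  dh <- crossprod(p$W2, dpre2)
  dpre1 <- nnSwishBackward(cache$hs$cache, dh)$dx
  dW1 <- dpre1 %*% t(cache$z)
  db1 <- rowSums(dpre1)
  dz <- crossprod(p$W1, dpre1)
  dx <- dy * cache$sb + array(rep(as.vector(dz / HW), each = HW), d)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

## --- dispatch ---------------------------------------------------------------

layerForward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      r <- nnConvForward(x, layer$params$W, layer$params$b, layer$stride,
                         layer$pad)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    dwconv = {
      r <- nnDepthwiseForward(x, layer$params$W, layer$params$b, layer$stride)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    bn = {
      r <- nnBatchNormForward(x, layer$params$gamma, layer$params$beta,
                              layer$running, training)
      layer$running <- r$running
      list(y = r$y, cache = r$cache, layer = layer)
    },
    relu = {
      r <- nnReluForward(x)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    swish = {
      r <- nnSwishForward(x)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    maxpool = {
      r <- nnMaxPoolForward(x, layer$k, layer$stride, layer$pad)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    avgpool = {
      r <- nnAvgPoolForward(x, layer$k)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    adaptpool = {
      r <- nnAdaptiveAvgPoolForward(x, layer$oh, layer$ow)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    dropout = {
      r <- nnDropoutForward(x, layer$rate, training)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(prod(d[-length(d)]), d[length(d)])
      list(y = y, cache = list(d = d), layer = layer)
    },
    dense = {
      r <- nnDenseForward(x, layer$params$W, layer$params$b)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    pscse = {
      r <- wfPscseFwd(x, layer$params, layer$merge)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    vattn = {
      r <- wfVattnFwd(x, layer$params)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    ln = {
      r <- nnLayerNormForward(x, layer$params$gamma, layer$params$beta)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    se = {
      r <- wfSeFwd(x, layer$params)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    res = {
      main <- seqForward(layer$main, x, training)
      skip <- if (is.null(layer$down)) list(y = x, caches = NULL, layers = NULL)
              else seqForward(layer$down, x, training)
      s <- main$y + skip$y
      act <- if (layer$finalRelu) nnReluForward(s) else list(y = s, cache = NULL)
      layer$main <- main$layers
      if (!is.null(layer$down)) layer$down <- skip$layers
      list(y = act$y,
           cache = list(main = main$caches, down = skip$caches,
                        act = act$cache),
           layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

layerBackward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      r <- nnConvBackward(cache, dy)
      list(dx = r$dx, grads = list(W = r$dW, b = r$db))
    },
    dwconv = {
      r <- nnDepthwiseBackward(cache, dy)
      list(dx = r$dx, grads = list(W = r$dW, b = r$db))
    },
    bn = {
      r <- nnBatchNormBackward(cache, dy)
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    relu = list(dx = nnReluBackward(cache, dy)$dx, grads = list()),
    swish = list(dx = nnSwishBackward(cache, dy)$dx, grads = list()),
    maxpool = list(dx = nnMaxPoolBackward(cache, dy)$dx, grads = list()),
    avgpool = list(dx = nnAvgPoolBackward(cache, dy)$dx, grads = list()),
    adaptpool = list(dx = nnAdaptiveAvgPoolBackward(cache, dy)$dx,
                     grads = list()),
    dropout = list(dx = nnDropoutBackward(cache, dy)$dx, grads = list()),
    flatten = {
      dx <- dy
      dim(dx) <- cache$d
      list(dx = dx, grads = list())
    },
    dense = {
      r <- nnDenseBackward(cache, dy)
      list(dx = r$dx, grads = list(W = r$dW, b = r$db))
    },
    pscse = {
      r <- wfPscseBwd(cache, dy, layer$params)
      list(dx = r$dx, grads = r$grads)
    },
    vattn = {
      r <- wfVattnBwd(cache, dy, layer$params)
      list(dx = r$dx, grads = r$grads)
    },
    ln = {
      r <- nnLayerNormBackward(cache, dy)
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    se = {
      r <- wfSeBwd(cache, dy, layer$params)
      list(dx = r$dx, grads = r$grads)
    },
    res = {
      ds <- if (layer$finalRelu) nnReluBackward(cache$act, dy)$dx else dy
      mainB <- seqBackward(layer$main, cache$main, ds)
      if (is.null(layer$down)) {
        dx <- mainB$dx + ds
        list(dx = dx, grads = list(main = mainB$grads))
      } else {
        downB <- seqBackward(layer$down, cache$down, ds)
        list(dx = mainB$dx + downB$dx,
             grads = list(main = mainB$grads, down = downB$grads))
      }
    },
    stop("unknown layer type: ", layer$type))
}

## Forward through a stack. Returns the output, per-layer caches, the
## (possibly state-updated) layers, and optionally each layer's output.
seqForward <- function(layers, x, training = FALSE, keepOutputs = FALSE) {
  caches <- vector("list", length(layers))
  outputs <- if (keepOutputs) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    r <- layerForward(layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
    if (keepOutputs) outputs[[i]] <- x
  }
  list(y = x, caches = caches, layers = layers, outputs = outputs)
}

## Backward through a stack; wantDyAt captures the gradient with respect to
## the *output* of the named layer indices (used by Grad-CAM).
seqBackward <- function(layers, caches, dy, wantDyAt = integer(0)) {
  grads <- vector("list", length(layers))
  dyAt <- list()
  for (i in rev(seq_along(layers))) {
    if (i %in% wantDyAt) dyAt[[as.character(i)]] <- dy
    r <- layerBackward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  names(grads) <- paste0("l", seq_along(layers))
  list(dx = dy, grads = grads, dyAt = dyAt)
}

seqParams <- function(layers) {
  out <- lapply(layers, function(l) {
    if (l$type == "res") {
      g <- list(main = seqParams(l$main))
      if (!is.null(l$down)) g$down <- seqParams(l$down)
      g
    } else l$params
  })
  names(out) <- paste0("l", seq_along(layers))
  out
}

seqSetParams <- function(layers, p) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "res") {
      layers[[i]]$main <- seqSetParams(layers[[i]]$main, p[[i]]$main)
      if (!is.null(layers[[i]]$down))
        layers[[i]]$down <- seqSetParams(layers[[i]]$down, p[[i]]$down)
    } else {
      layers[[i]]$params <- p[[i]]
    }
  }
  layers
}

## Static shape inference: input c(H, W, C) -> output c(H, W, C) for
## feature-map stacks (no computation).
shapeAfterLayer <- function(layer, s) {
  H <- s[1]; W <- s[2]; C <- s[3]
  pd <- function(k, pad) if (identical(pad, "same")) (k - 1L) %/% 2L
                         else as.integer(pad)
  switch(layer$type,
    conv = {
      p <- pd(layer$k, layer$pad)
      c(convOutLen(H, layer$k, layer$stride, p),
        convOutLen(W, layer$k, layer$stride, p), layer$outC)
    },
    dwconv = {
      p <- (layer$k - 1L) %/% 2L
      c(convOutLen(H, layer$k, layer$stride, p),
        convOutLen(W, layer$k, layer$stride, p), C)
    },
    maxpool = c(convOutLen(H, layer$k, layer$stride, layer$pad),
                convOutLen(W, layer$k, layer$stride, layer$pad), C),
    avgpool = c(H %/% layer$k, W %/% layer$k, C),
    adaptpool = c(layer$oh, layer$ow, C),
    res = shapeInfer(layer$main, s),
    s)
}

shapeInfer <- function(layers, s) {
  for (l in layers) s <- shapeAfterLayer(l, s)
  s
}

## Indices of top-level convolution layers in a stack (Grad-CAM taps).
topLevelConvIdx <- function(layers) {
  which(vapply(layers, function(l) l$type %in% c("conv", "dwconv"), logical(1)))
}
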