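## Custom computational blocks: ConvBlock, channel / spatial
## squeeze-and-excitation (cSE / sSE), their parallel merge (P_scSE), axial
## self-attention, and the adaptive-gated MLP that consumes the body-map
## location encoding.
##
## Each block exists in two forms:
##   * an internal batched form (arrays (H, W, C, N) / matrices (F, N)) with
##     an exact hand-derived backward pass, used by the fusion network;
##   * an exported single-sample functional form following the (C, H, W)
##     feature-map convention, used for direct experimentation and testing.

## ===== ConvBlock ============================================================

wfConvBlockFwd <- function(x, p, stride = 1L) {
  cv <- nnConvForward(x, p$W, p$b, stride = stride, pad = "same")
  rl <- nnReluForward(cv$y)
  list(y = rl$y, cache = list(cv = cv$cache, rl = rl$cache))
}

wfConvBlockBwd <- function(cache, dy) {
  dr <- nnReluBackward(cache$rl, dy)
  dc <- nnConvBackward(cache$cv, dr$dx)
  list(dx = dc$dx, grads = list(W = dc$dW, b = dc$db))
}

## ===== cSE: channel squeeze-and-excitation =================================

## p: W1 (Cr x C), b1, W2 (C x Cr), b2
wfCseFwd <- function(x, p) {
  d <- dim(x); HW <- d[1] * d[2]
  z <- matrix(colMeans(matrix(x, HW, d[3] * d[4])), d[3], d[4])  # (C, N)
  h1 <- p$W1 %*% z + p$b1
  h <- pmax(h1, 0)
  s <- nnSigmoid(p$W2 %*% h + p$b2)                               # (C, N)
  sb <- array(rep(as.vector(s), each = HW), d)
  list(y = x * sb,
       cache = list(x = x, z = z, h1 = h1, h = h, s = s, sb = sb, d = d))
}

wfCseBwd <- function(cache, dy, p) {
  d <- cache$d; HW <- d[1] * d[2]
  ds <- matrix(colSums(matrix(dy * cache$x, HW, d[3] * d[4])), d[3], d[4])
  dpre2 <- ds * cache$s * (1 - cache$s)
  dW2 <- dpre2 %*% t(cache$h)
  db2 <- rowSums(dpre2)
  dh <- crossprod(p$W2, dpre2)
  dpre1 <- dh * (cache$h1 > 0)
  dW1 <- dpre1 %*% t(cache$z)
  db1 <- rowSums(dpre1)
  dz <- crossprod(p$W1, dpre1)
  dx <- dy * cache$sb + array(rep(as.vector(dz / HW), each = HW), d)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

## ===== sSE: spatial squeeze-and-excitation =================================

## p: w (C), b (scalar) — a 1x1, C -> 1 projection.
wfSseFwd <- function(x, p) {
  d <- dim(x); HWN <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), HWN, d[3])
  pre <- as.vector(xm %*% p$w) + p$b
  q <- nnSigmoid(pre)                                 # length H*W*N
  qb <- aperm(array(q, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(y = x * qb, cache = list(x = x, xm = xm, q = q, qb = qb, d = d))
}

wfSseBwd <- function(cache, dy, p) {
  d <- cache$d; HWN <- d[1] * d[2] * d[4]
  dq <- rowSums(matrix(aperm(dy * cache$x, c(1, 2, 4, 3)), HWN, d[3]))
  dpre <- dq * cache$q * (1 - cache$q)
  dw <- as.vector(crossprod(cache$xm, dpre))
  db <- sum(dpre)
  dxm <- dpre %*% t(p$w)                              # (HWN, C)
  dx <- dy * cache$qb +
    aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, grads = list(w = dw, b = db))
}

## ===== P_scSE: parallel merge ==============================================

## merge: "maxout_add" (max(a,b) + a + b), "max", or "add".
wfPscseFwd <- function(x, p, merge = "maxout_add") {
  a <- wfCseFwd(x, p$cse)
  b <- wfSseFwd(x, p$sse)
  y <- switch(merge,
    maxout_add = pmax(a$y, b$y) + a$y + b$y,
    max = pmax(a$y, b$y),
    add = a$y + b$y,
    stop("unknown P_scSE merge mode: ", merge))
  list(y = y, cache = list(a = a, b = b, merge = merge,
                           amax = a$y >= b$y))
}

wfPscseBwd <- function(cache, dy, p) {
  da <- switch(cache$merge,
    maxout_add = dy * (1 + cache$amax),
    max = dy * cache$amax,
    add = dy)
  db <- switch(cache$merge,
    maxout_add = dy * (1 + !cache$amax),
    max = dy * !cache$amax,
    add = dy)
  ga <- wfCseBwd(cache$a$cache, da, p$cse)
  gb <- wfSseBwd(cache$b$cache, db, p$sse)
  list(dx = ga$dx + gb$dx, grads = list(cse = ga$grads, sse = gb$grads))
}

## ===== axial attention ======================================================

## Scaled dot-product self-attention over the rows of a token matrix X (L, F)
## with learned projections Wq, Wk, Wv (F, F); optional residual connection.
attnSeqFwd <- function(X, p, residual = TRUE) {
  f <- ncol(X)
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  S <- tcrossprod(Q, K) / sqrt(f)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  A <- E / rowSums(E)
  att <- A %*% V
  Y <- if (residual) X + att else att
  list(y = Y, cache = list(X = X, Q = Q, K = K, V = V, A = A,
                           residual = residual, f = f))
}

attnSeqBwd <- function(cache, dY, p) {
  A <- cache$A; f <- cache$f
  dV <- crossprod(A, dY)
  dA <- tcrossprod(dY, cache$V)
  dS <- A * (dA - rowSums(dA * A))
  dQ <- dS %*% cache$K / sqrt(f)
  dK <- crossprod(dS, cache$Q) / sqrt(f)
  dX <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  if (cache$residual) dX <- dX + dY
  list(dx = dX,
       grads = list(Wq = crossprod(cache$X, dQ),
                    Wk = crossprod(cache$X, dK),
                    Wv = crossprod(cache$X, dV)))
}

## Axial attention over one spatial axis of a batched feature map (H,W,C,N):
## tokens run along `axis`, features are the channels, and the attention is
## applied independently to every slice of the other axis and batch element.
wfAxialMapFwd <- function(x, p, axis = c("height", "width"), residual = TRUE) {
  axis <- match.arg(axis)
  d <- dim(x)
  y <- array(0, d)
  caches <- vector("list", 0L)
  k <- 0L
  nOther <- if (axis == "height") d[2] else d[1]
  for (n in seq_len(d[4])) for (o in seq_len(nOther)) {
    X <- if (axis == "height") array(x[, o, , n], c(d[1], d[3]))
         else array(x[o, , , n], c(d[2], d[3]))
    r <- attnSeqFwd(X, p, residual)
    k <- k + 1L
    caches[[k]] <- r$cache
    if (axis == "height") y[, o, , n] <- r$y else y[o, , , n] <- r$y
  }
  list(y = y, cache = list(slices = caches, axis = axis, d = d))
}

wfAxialMapBwd <- function(cache, dy, p) {
  d <- cache$d; axis <- cache$axis
  dx <- array(0, d)
  grads <- list(Wq = 0 * p$Wq, Wk = 0 * p$Wk, Wv = 0 * p$Wv)
  k <- 0L
  nOther <- if (axis == "height") d[2] else d[1]
  for (n in seq_len(d[4])) for (o in seq_len(nOther)) {
    dY <- if (axis == "height") array(dy[, o, , n], c(d[1], d[3]))
          else array(dy[o, , , n], c(d[2], d[3]))
    k <- k + 1L
    r <- attnSeqBwd(cache$slices[[k]], dY, p)
    grads$Wq <- grads$Wq + r$grads$Wq
    grads$Wk <- grads$Wk + r$grads$Wk
    grads$Wv <- grads$Wv + r$grads$Wv
    if (axis == "height") dx[, o, , n] <- r$dx else dx[o, , , n] <- r$dx
  }
  list(dx = dx, grads = grads)
}

## Axial attention for flat feature vectors: the F-length vector is reshaped
## into an s x s grid (s = ceiling(sqrt(F)), zero-padded), attention runs
## first along one grid axis then the other, and the grid is flattened back.
vattnGridSide <- function(f) as.integer(ceiling(sqrt(f)))

## x: (F, N); p: list(p1, p2) each with Wq/Wk/Wv of dim (s, s).
wfVattnFwd <- function(x, p, residual = TRUE) {
  f <- nrow(x); N <- ncol(x)
  s <- vattnGridSide(f)
  y <- matrix(0, f, N)
  caches <- vector("list", N)
  for (n in seq_len(N)) {
    vp <- c(x[, n], numeric(s * s - f))
    G <- matrix(vp, s, s)
    r1 <- attnSeqFwd(G, p$p1, residual)
    r2 <- attnSeqFwd(t(r1$y), p$p2, residual)
    out <- as.vector(t(r2$y))
    y[, n] <- out[seq_len(f)]
    caches[[n]] <- list(c1 = r1$cache, c2 = r2$cache)
  }
  list(y = y, cache = list(slices = caches, f = f, s = s))
}

wfVattnBwd <- function(cache, dy, p) {
  f <- cache$f; s <- cache$s; N <- ncol(dy)
  dx <- matrix(0, f, N)
  g0 <- function(q) list(Wq = 0 * q$Wq, Wk = 0 * q$Wk, Wv = 0 * q$Wv)
  grads <- list(p1 = g0(p$p1), p2 = g0(p$p2))
  for (n in seq_len(N)) {
    dout <- c(dy[, n], numeric(s * s - f))
    dY2 <- matrix(dout, s, s, byrow = TRUE)
    r2 <- attnSeqBwd(cache$slices[[n]]$c2, dY2, p$p2)
    dY1 <- t(r2$dx)
    r1 <- attnSeqBwd(cache$slices[[n]]$c1, dY1, p$p1)
    dG <- r1$dx
    dv <- as.vector(dG)
    dx[, n] <- dv[seq_len(f)]
    for (w in c("Wq", "Wk", "Wv")) {
      grads$p1[[w]] <- grads$p1[[w]] + r1$grads[[w]]
      grads$p2[[w]] <- grads$p2[[w]] + r2$grads[[w]]
    }
  }
  list(dx = dx, grads = grads)
}

## ===== adaptive-gated MLP ===================================================

## Location branch: u = ReLU(Win.loc + bin); split u into (u1, u2);
## g = sigmoid(Wg.axial(u2) + bg); y = Wout.(u1 * g) + bout.
## p: Win (2m x L), bin, attn (vattn params over m), Wg (m x m), bg,
##    Wout (out x m), bout.
wfGmlpFwd <- function(loc, p, residual = TRUE) {
  pre <- p$Win %*% loc + p$bin
  u <- pmax(pre, 0)
  m <- nrow(u) %/% 2L
  u1 <- u[seq_len(m), , drop = FALSE]
  u2 <- u[m + seq_len(m), , drop = FALSE]
  at <- wfVattnFwd(u2, p$attn, residual)
  gpre <- p$Wg %*% at$y + p$bg
  g <- nnSigmoid(gpre)
  h <- u1 * g
  y <- p$Wout %*% h + p$bout
  list(y = y, cache = list(loc = loc, pre = pre, u1 = u1, u2 = u2, at = at,
                           g = g, h = h, m = m, residual = residual))
}

wfGmlpBwd <- function(cache, dy, p) {
  m <- cache$m
  dWout <- dy %*% t(cache$h)
  dbout <- rowSums(dy)
  dh <- crossprod(p$Wout, dy)
  du1 <- dh * cache$g
  dg <- dh * cache$u1
  dgpre <- dg * cache$g * (1 - cache$g)
  dWg <- dgpre %*% t(cache$at$y)
  dbg <- rowSums(dgpre)
  dat <- crossprod(p$Wg, dgpre)
  vb <- wfVattnBwd(cache$at$cache, dat, p$attn)
  du2 <- vb$dx
  du <- rbind(du1, du2)
  dpre <- du * (cache$pre > 0)
  dWin <- dpre %*% t(cache$loc)
  dbin <- rowSums(dpre)
  dloc <- crossprod(p$Win, dpre)
  list(dx = dloc,
       grads = list(Win = dWin, bin = dbin, attn = vb$grads,
                    Wg = dWg, bg = dbg, Wout = dWout, bout = dbout))
}

## ===== parameter constructors ==============================================

#' Parameters for a ConvBlock
#'
#' A ConvBlock is a same-padded 2-D convolution followed by a ReLU.
#'
#' @param inChannels,outChannels Input / output channel counts.
#' @param kernel Odd kernel size (default 3).
#' @param seed Integer seed for the He-uniform initialisation.
#' @return A parameter list with elements `W` (kh, kw, Cin, Cout) and `b`.
#' @export
convBlockParams <- function(inChannels, outChannels, kernel = 3L, seed = 1L) {
  withSeed(seed, {
    list(W = heInit(c(kernel, kernel, inChannels, outChannels),
                    kernel * kernel * inChannels),
         b = numeric(outChannels))
  })
}

#' Parameters for channel squeeze-and-excitation (cSE)
#'
#' The excitation bottleneck reduces `channels` by the reduction ratio `r`
#' (ceiling rounding, minimum width 1).
#'
#' @param channels Number of feature-map channels.
#' @param r Reduction ratio (default 16, the conventional SE default).
#' @param seed Integer seed.
#' @return Parameter list `W1`, `b1`, `W2`, `b2`.
#' @export
cseParams <- function(channels, r = 16L, seed = 1L) {
  cr <- max(1L, as.integer(ceiling(channels / r)))
  withSeed(seed, {
    list(W1 = heInit(c(cr, channels), channels), b1 = rep(0.01, cr),
         W2 = heInit(c(channels, cr), cr), b2 = numeric(channels))
  })
}

#' Parameters for spatial squeeze-and-excitation (sSE)
#'
#' @param channels Number of feature-map channels.
#' @param seed Integer seed.
#' @return Parameter list `w` (length `channels`) and scalar `b`.
#' @export
sseParams <- function(channels, seed = 1L) {
  withSeed(seed, list(w = as.vector(heInit(channels, channels)), b = 0))
}

#' Parameters for the parallel squeeze-and-excitation block (P_scSE)
#'
#' @inheritParams cseParams
#' @return Parameter list with sub-lists `cse` and `sse`.
#' @export
pScSEParams <- function(channels, r = 16L, seed = 1L) {
  list(cse = cseParams(channels, r, seed), sse = sseParams(channels, seed + 1L))
}

#' Parameters for axial attention
#'
#' @param featureDim Feature (channel) dimension of the tokens.
#' @param seed Integer seed.
#' @return Parameter list `Wq`, `Wk`, `Wv`, each `featureDim` x `featureDim`.
#' @export
axialAttentionParams <- function(featureDim, seed = 1L) {
  withSeed(seed, {
    sc <- sqrt(6 / (2 * featureDim))
    mk <- function() array(stats::runif(featureDim^2, -sc, sc),
                           c(featureDim, featureDim))
    list(Wq = mk(), Wk = mk(), Wv = mk())
  })
}

vattnParams <- function(f, seed = 1L) {
  s <- vattnGridSide(f)
  list(p1 = axialAttentionParams(s, seed), p2 = axialAttentionParams(s, seed + 1L))
}

#' Parameters for the adaptive-gated MLP location branch
#'
#' @param locationDim Length of the one-hot location encoding (484 for the
#'   canonical body map).
#' @param hidden Width of the hidden expansion (split in half between the
#'   value path and the gate path); must be even.
#' @param outDim Output width concatenated into the classifier head.
#' @param seed Integer seed.
#' @return Parameter list `Win`, `bin`, `attn`, `Wg`, `bg`, `Wout`, `bout`.
#' @export
gatedMLPParams <- function(locationDim = 484L, hidden = 128L, outDim = 32L,
                           seed = 1L) {
  wfAssert(hidden %% 2L == 0L, "gated MLP hidden width must be even")
  m <- hidden %/% 2L
  withSeed(seed, {
    list(Win = heInit(c(hidden, locationDim), locationDim),
         bin = numeric(hidden),
         attn = vattnParams(m, seed + 1L),
         Wg = heInit(c(m, m), m), bg = numeric(m),
         Wout = heInit(c(outDim, m), m), bout = numeric(outDim))
  })
}

## ===== exported single-sample API ==========================================

asHWCN <- function(x) {
  wfAssert(length(dim(x)) == 3L, "expected a (C, H, W) feature map")
  d <- dim(x)
  array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1L))
}

asCHW <- function(x) {
  d <- dim(x)
  array(aperm(x[, , , 1, drop = FALSE], c(3, 1, 2, 4)), c(d[3], d[1], d[2]))
}

#' ConvBlock: convolution + ReLU
#'
#' Applies a same-padded 2-D convolution followed by a ReLU to a single
#' feature map.
#'
#' @param x Numeric array of dim (C, H, W).
#' @param params Parameters from [convBlockParams()].
#' @return Numeric array (Cout, H, W), all entries non-negative.
#' @examples
#' p <- convBlockParams(2, 4, seed = 1)
#' y <- convBlock(array(rnorm(2 * 5 * 5), c(2, 5, 5)), p)
#' all(y >= 0)
#' @export
convBlock <- function(x, params) {
  asCHW(wfConvBlockFwd(asHWCN(x), params)$y)
}

#' Channel squeeze-and-excitation (cSE)
#'
#' Rescales each channel of a feature map by a learned sigmoid gate computed
#' from the channel-wise spatial means: `s = sigmoid(W2 relu(W1 z))`,
#' `y[c] = s[c] x[c]`.
#'
#' @param x Numeric array of dim (C, H, W).
#' @param params Parameters from [cseParams()].
#' @return Array of the same shape as `x`.
#' @export
cse <- function(x, params) {
  asCHW(wfCseFwd(asHWCN(x), params)$y)
}

#' Spatial squeeze-and-excitation (sSE)
#'
#' Rescales each spatial position of a feature map by a learned sigmoid gate
#' computed by a 1x1, C-to-1 projection: `q = sigmoid(conv1x1(x))`,
#' `y[c,h,w] = q[h,w] x[c,h,w]`.
#'
#' @param x Numeric array of dim (C, H, W).
#' @param params Parameters from [sseParams()].
#' @return Array of the same shape as `x`.
#' @export
sse <- function(x, params) {
  asCHW(wfSseFwd(asHWCN(x), params)$y)
}

#' Parallel squeeze-and-excitation (P_scSE)
#'
#' Runs cSE and sSE in parallel on the same input and merges the two outputs.
#' The default merge combines max-out and addition:
#' `max(a, b) + (a + b)`; `"max"` and `"add"` are available as alternatives.
#'
#' @param x Numeric array of dim (C, H, W).
#' @param params Parameters from [pScSEParams()].
#' @param merge One of `"maxout_add"`, `"max"`, `"add"`.
#' @return Array of the same shape as `x`.
#' @export
pScSE <- function(x, params, merge = c("maxout_add", "max", "add")) {
  merge <- match.arg(merge)
  asCHW(wfPscseFwd(asHWCN(x), params, merge)$y)
}

#' Axial self-attention
#'
#' Scaled dot-product self-attention restricted to one axis at a time. For a
#' token matrix (L x F), `axis = "sequence"` attends over the L rows. For a
#' (C, H, W) feature map, `axis = "height"` or `"width"` attends along that
#' spatial axis independently for every slice of the other axis, with the
#' channels as token features. A residual connection adds the input by
#' default.
#'
#' @param x Token matrix (L, F) or feature-map array (C, H, W).
#' @param params Parameters from [axialAttentionParams()] with `featureDim`
#'   equal to F (token matrices) or C (feature maps).
#' @param axis `"sequence"` for matrices; `"height"` or `"width"` for maps.
#' @param residual Add the input to the attention output (default TRUE).
#' @return Same shape as `x`.
#' @export
axialAttention <- function(x, params, axis = c("sequence", "height", "width"),
                           residual = TRUE) {
  axis <- match.arg(axis)
  if (is.matrix(x)) {
    wfAssert(axis == "sequence", "matrix input requires axis = \"sequence\"")
    return(attnSeqFwd(x, params, residual)$y)
  }
  wfAssert(length(dim(x)) == 3L, "expected a matrix or a (C, H, W) array")
  wfAssert(axis %in% c("height", "width"),
           "feature-map input requires axis \"height\" or \"width\"")
  asCHW(wfAxialMapFwd(asHWCN(x), params, axis, residual)$y)
}

#' Adaptive-gated MLP for the location encoding
#'
#' Processes a one-hot body-map location vector through a linear expansion
#' with ReLU, splits the hidden features into a value half and a gate half,
#' applies axial attention to the gate half (reshaped to a square grid), and
#' multiplies the value half by the resulting sigmoid gate before the output
#' projection. A closed gate (sigmoid near 0) blocks all location signal.
#'
#' @param loc Numeric vector, length equal to `locationDim` of `params`.
#' @param params Parameters from [gatedMLPParams()].
#' @return Numeric vector of length `outDim`.
#' @export
adaptiveGatedMLP <- function(loc, params) {
  wfAssert(length(loc) == ncol(params$Win),
           "location vector length ", length(loc),
           " does not match configured dimension ", ncol(params$Win))
  as.vector(wfGmlpFwd(matrix(loc, ncol = 1), params)$y)
}
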