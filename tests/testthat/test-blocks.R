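test_that("ConvBlock matches a naive convolution oracle and rectifies", {
  set.seed(1)
  p <- convBlockParams(3, 4, seed = 2)
  x <- array(rnorm(3 * 5 * 6), c(3, 5, 6))
  y <- convBlock(x, p)
  expect_equal(y, pmax(oracleConv(x, p$W, p$b), 0), tolerance = 1e-5)
  expect_true(all(y >= 0))
  ## all-negative input through an identity kernel dies under ReLU
  pid <- list(W = array(0, c(1, 1, 2, 2)), b = c(0, 0))
  pid$W[1, 1, 1, 1] <- 1; pid$W[1, 1, 2, 2] <- 1
  xneg <- array(-abs(rnorm(2 * 4 * 4)), c(2, 4, 4))
  expect_equal(convBlock(xneg, pid), 0 * xneg)
  ## identity kernel on non-negative input is the identity
  xpos <- abs(array(rnorm(2 * 4 * 4), c(2, 4, 4)))
  expect_equal(convBlock(xpos, pid), xpos, tolerance = 1e-12)
  expect_error(convBlock(array(0, c(5, 4, 4)), p), "channels")
})

test_that("cSE matches the per-channel scale oracle and saturates correctly", {
  set.seed(2)
  p <- cseParams(6, r = 2, seed = 3)
  x <- array(rnorm(6 * 4 * 5), c(6, 4, 5))
  expect_equal(cse(x, p), oracleCse(x, p), tolerance = 1e-5)
  ## large positive bias saturates the gate at 1; large negative at 0
  pOpen <- p; pOpen$b2 <- rep(50, 6)
  expect_equal(cse(x, pOpen), x, tolerance = 1e-6)
  pShut <- p; pShut$b2 <- rep(-50, 6)
  expect_equal(max(abs(cse(x, pShut))), 0, tolerance = 1e-6)
})

test_that("sSE matches the element-wise oracle and its gates behave", {
  set.seed(3)
  p <- sseParams(5, seed = 4)
  x <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  expect_equal(sse(x, p), oracleSse(x, p), tolerance = 1e-5)
  ## zero projection: q = sigmoid(0) = 0.5 everywhere
  expect_equal(sse(x, list(w = numeric(5), b = 0)), x / 2)
  expect_equal(sse(x, list(w = numeric(5), b = 50)), x, tolerance = 1e-6)
})

test_that("P_scSE merges cSE and sSE via max-out plus addition", {
  set.seed(4)
  p <- pScSEParams(4, r = 2, seed = 5)
  x <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  a <- oracleCse(x, p$cse)
  b <- oracleSse(x, p$sse)
  expect_equal(pScSE(x, p), pmax(a, b) + a + b, tolerance = 1e-5)
  expect_equal(pScSE(x, p, merge = "max"), pmax(a, b), tolerance = 1e-5)
  expect_equal(pScSE(x, p, merge = "add"), a + b, tolerance = 1e-5)
  ## zero input maps to zero; identical gate effects triple
  expect_equal(pScSE(0 * x, p), 0 * x)
})

test_that("axial attention equals full attention when one axis is trivial", {
  set.seed(5)
  C <- 5; W <- 7
  p <- axialAttentionParams(C, seed = 6)
  x <- array(rnorm(C * 1 * W), c(C, 1, W))     # H == 1 feature map
  y <- axialAttention(x, p, axis = "width")
  X <- t(array(x[, 1, ], c(C, W)))             # W tokens x C features
  expect_equal(t(array(y[, 1, ], c(C, W))), oracleAttn(X, p), tolerance = 1e-5)
})

test_that("attention weights normalise and a single token passes its value", {
  set.seed(6)
  p <- axialAttentionParams(4, seed = 7)
  X <- matrix(rnorm(24), 6, 4)
  f <- woundfusion:::attnSeqFwd(X, p)
  expect_equal(rowSums(f$cache$A), rep(1, 6), tolerance = 1e-12)
  ## single token, no residual: output is exactly the value projection
  X1 <- matrix(rnorm(4), 1, 4)
  expect_equal(axialAttention(X1, p, "sequence", residual = FALSE),
               X1 %*% p$Wv, tolerance = 1e-12)
})

test_that("axial attention is equivariant over slices of the other axis", {
  set.seed(7)
  p <- axialAttentionParams(3, seed = 8)
  x <- array(rnorm(3 * 4 * 6), c(3, 4, 6))
  y <- axialAttention(x, p, axis = "height")
  perm <- sample(6)
  yp <- axialAttention(x[, , perm], p, axis = "height")
  expect_equal(yp, y[, , perm], tolerance = 1e-12)
})

test_that("adaptive-gated MLP matches its step-by-step oracle and gates", {
  set.seed(8)
  p <- gatedMLPParams(30, hidden = 32, outDim = 8, seed = 9)
  loc <- numeric(30); loc[17] <- 1
  expect_equal(adaptiveGatedMLP(loc, p), oracleGmlp(loc, p), tolerance = 1e-5)
  ## gate driven shut: only the output bias survives, location is blocked
  pShut <- p; pShut$bg <- rep(-50, length(p$bg))
  o1 <- adaptiveGatedMLP(loc, pShut)
  loc2 <- numeric(30); loc2[3] <- 1
  expect_equal(o1, adaptiveGatedMLP(loc2, pShut), tolerance = 1e-8)
  expect_equal(o1, as.vector(p$bout), tolerance = 1e-8)
  ## gate driven open: output = Wout u1 + bout
  pOpen <- p; pOpen$bg <- rep(50, length(p$bg))
  u <- pmax(as.vector(p$Win %*% loc + p$bin), 0)
  u1 <- u[seq_len(length(u) / 2)]
  expect_equal(adaptiveGatedMLP(loc, pOpen),
               as.vector(p$Wout %*% u1 + p$bout), tolerance = 1e-6)
  expect_error(adaptiveGatedMLP(numeric(29), p), "does not match")
})

test_that("blocks preserve shapes over randomized small inputs", {
  set.seed(9)
  for (rep in 1:6) {
    C <- sample(1:8, 1); H <- sample(1:8, 1); W <- sample(1:8, 1)
    x <- array(rnorm(C * H * W), c(C, H, W))
    expect_equal(dim(cse(x, cseParams(C, r = 4, seed = rep))), c(C, H, W))
    expect_equal(dim(sse(x, sseParams(C, seed = rep))), c(C, H, W))
    expect_equal(dim(pScSE(x, pScSEParams(C, r = 4, seed = rep))), c(C, H, W))
    pa <- axialAttentionParams(C, seed = rep)
    expect_equal(dim(axialAttention(x, pa, "height")), c(C, H, W))
    expect_equal(dim(axialAttention(x, pa, "width")), c(C, H, W))
    k <- sample(1:4, 1)
    pc <- convBlockParams(C, k, seed = rep)
    expect_equal(dim(convBlock(x, pc)), c(k, H, W))
  }
})

test_that("gates bound the excitation outputs by the input", {
  set.seed(10)
  x <- array(rnorm(5 * 6 * 6), c(5, 6, 6))
  pc <- cseParams(5, r = 2, seed = 1)
  ps <- sseParams(5, seed = 2)
  pp <- list(cse = pc, sse = ps)
  expect_true(all(abs(cse(x, pc)) <= abs(x) + 1e-12))
  expect_true(all(abs(sse(x, ps)) <= abs(x) + 1e-12))
  expect_true(all(abs(pScSE(x, pp)) <= 3 * abs(x) + 1e-12))
})

test_that("every block's backward pass matches finite differences", {
  set.seed(11)
  eps <- 1e-6
  fdCheck <- function(lossFn, gradVal, theta, k = 3L) {
    idx <- sample(length(theta), min(k, length(theta)))
    for (i in idx) {
      th2 <- theta; th2[i] <- th2[i] + eps
      fd <- (lossFn(th2) - lossFn(theta)) / eps
      expect_equal(gradVal[i], fd, tolerance = 1e-3)
    }
  }
  ## ConvBlock input gradient
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  p <- convBlockParams(3, 5, seed = 12)
  fw <- woundfusion:::wfConvBlockFwd(x, p)
  bw <- woundfusion:::wfConvBlockBwd(fw$cache, 2 * fw$y)
  fdCheck(function(z) sum(woundfusion:::wfConvBlockFwd(
    array(z, dim(x)), p)$y^2), bw$dx, x)
  ## P_scSE input gradient
  pp <- pScSEParams(3, r = 2, seed = 13)
  xp <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  fs <- woundfusion:::wfPscseFwd(xp, pp)
  bs <- woundfusion:::wfPscseBwd(fs$cache, 2 * fs$y, pp)
  fdCheck(function(z) sum(woundfusion:::wfPscseFwd(
    array(z, dim(xp)), pp)$y^2), bs$dx, xp)
  ## axial attention parameter gradient
  pa <- axialAttentionParams(4, seed = 14)
  X <- matrix(rnorm(20), 5, 4)
  fa <- woundfusion:::attnSeqFwd(X, pa)
  ba <- woundfusion:::attnSeqBwd(fa$cache, 2 * fa$y, pa)
  fdCheck(function(w) {
    p2 <- pa; p2$Wq <- matrix(w, 4, 4)
    sum(woundfusion:::attnSeqFwd(X, p2)$y^2)
  }, ba$grads$Wq, pa$Wq)
  ## gated MLP parameter gradient
  pg <- gatedMLPParams(12, hidden = 8, outDim = 4, seed = 15)
  lc <- matrix(0, 12, 2); lc[5, 1] <- 1; lc[9, 2] <- 1
  fg <- woundfusion:::wfGmlpFwd(lc, pg)
  bg <- woundfusion:::wfGmlpBwd(fg$cache, 2 * fg$y, pg)
  fdCheck(function(w) {
    p2 <- pg; p2$Wout <- matrix(w, dim(pg$Wout)[1], dim(pg$Wout)[2])
    sum(woundfusion:::wfGmlpFwd(lc, p2)$y^2)
  }, bg$grads$Wout, pg$Wout)
})
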