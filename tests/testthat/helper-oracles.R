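## Brute-force oracles for every custom block, written as explicit loops /
## matrix arithmetic independent of the implementation.

oracleConv <- function(x, W, b) {
  d <- dim(x); k <- dim(W)[1]; Cout <- dim(W)[4]
  p <- (k - 1) %/% 2
  xp <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p))
  xp[, p + seq_len(d[2]), p + seq_len(d[3])] <- x
  y <- array(0, c(Cout, d[2], d[3]))
  for (oc in seq_len(Cout)) for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    s <- b[oc]
    for (di in seq_len(k)) for (dj in seq_len(k)) for (ci in seq_len(d[1]))
      s <- s + xp[ci, i + di - 1, j + dj - 1] * W[di, dj, ci, oc]
    y[oc, i, j] <- s
  }
  y
}

oracleCse <- function(x, p) {
  C <- dim(x)[1]
  z <- vapply(seq_len(C), function(c) mean(x[c, , ]), numeric(1))
  h <- pmax(as.vector(p$W1 %*% z + p$b1), 0)
  s <- 1 / (1 + exp(-(as.vector(p$W2 %*% h + p$b2))))
  y <- x
  for (c in seq_len(C)) y[c, , ] <- s[c] * x[c, , ]
  y
}

oracleSse <- function(x, p) {
  d <- dim(x)
  y <- x
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    q <- 1 / (1 + exp(-(sum(p$w * x[, i, j]) + p$b)))
    y[, i, j] <- q * x[, i, j]
  }
  y
}

oracleAttn <- function(X, p, residual = TRUE) {
  f <- ncol(X)
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  S <- Q %*% t(K) / sqrt(f)
  A <- t(apply(S, 1, function(r) {
    e <- exp(r - max(r)); e / sum(e)
  }))
  if (nrow(S) == 1L) A <- matrix(1, 1, 1)
  out <- A %*% V
  if (residual) X + out else out
}

oracleGmlp <- function(loc, p) {
  u <- pmax(as.vector(p$Win %*% loc + p$bin), 0)
  m <- length(u) / 2
  u1 <- u[1:m]; u2 <- u[m + 1:m]
  s <- ceiling(sqrt(m))
  vp <- c(u2, numeric(s * s - m))
  G <- matrix(vp, s, s)
  G1 <- oracleAttn(G, p$attn$p1)
  G2 <- oracleAttn(t(G1), p$attn$p2)
  a2 <- as.vector(t(G2))[1:m]
  g <- 1 / (1 + exp(-(as.vector(p$Wg %*% a2 + p$bg))))
  as.vector(p$Wout %*% (u1 * g) + p$bout)
}
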