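tinyCfg <- function(...) {
  args <- utils::modifyList(
    list(numClasses = 4L, imageSize = 32L, dropout = 0), list(...))
  do.call(networkConfig, args)
}

test_that("forward contract: logits shape, finiteness, location requirement", {
  net <- buildFusionNetwork(tinyCfg(numClasses = 6L, useLocation = TRUE),
                            seed = 1)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  loc <- matrix(0, 484, 2); loc[c(135, 300), c(1, 2)] <- diag(2)[, 1]
  loc[135, 1] <- 1; loc[300, 2] <- 1
  lg <- predictLogits(net, x, loc)
  expect_equal(dim(lg), c(6L, 2L))
  expect_true(all(is.finite(lg)))
  expect_error(predictLogits(net, x), "locations are required")
  ## integer locations are encoded through the body map
  bm <- canonicalBodyMap()
  lg2 <- predictLogits(net, x, c(135L, 300L), bodyMap = bm)
  expect_equal(lg2, lg)
})

test_that("inference is deterministic with dropout disabled", {
  net <- buildFusionNetwork(tinyCfg(dropout = 0.5), seed = 2)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  expect_identical(predictLogits(net, x), predictLogits(net, x))
})

test_that("a closed location gate blocks all location influence", {
  net <- buildFusionNetwork(tinyCfg(useLocation = TRUE), seed = 3)
  net@gmlp$bg[] <- -1e4               # force the sigmoid gate to 0
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  bm <- canonicalBodyMap()
  l1 <- predictLogits(net, x, 135L, bodyMap = bm)
  l2 <- predictLogits(net, x, 402L, bodyMap = bm)
  expect_equal(l1, l2, tolerance = 1e-10)
  ## and with an untouched gate the location does matter
  net0 <- buildFusionNetwork(tinyCfg(useLocation = TRUE), seed = 3)
  woundfusion:::withSeed(4, {
    net0@outDense[[1]]$params$W[] <- rnorm(length(net0@outDense[[1]]$params$W),
                                           0, 0.1)
  })
  expect_false(isTRUE(all.equal(predictLogits(net0, x, 135L, bodyMap = bm),
                                predictLogits(net0, x, 402L, bodyMap = bm))))
})

test_that("toggling the location branch leaves the image path untouched", {
  nOn <- buildFusionNetwork(tinyCfg(useLocation = TRUE), seed = 5)
  nOff <- buildFusionNetwork(tinyCfg(useLocation = FALSE), seed = 5)
  pOn <- woundfusion:::netParams(nOn)
  pOff <- woundfusion:::netParams(nOff)
  expect_identical(pOn$branches, pOff$branches)
  expect_identical(pOn$aggregation, pOff$aggregation)
  expect_identical(pOn$dense0, pOff$dense0)
  expect_identical(pOn$head, pOff$head)
})

test_that("logits are equivariant under permuting output-layer rows", {
  net <- buildFusionNetwork(tinyCfg(), seed = 6)
  woundfusion:::withSeed(7, {
    net@outDense[[1]]$params$W[] <- rnorm(length(net@outDense[[1]]$params$W))
    net@outDense[[1]]$params$b[] <- rnorm(4)
  })
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  lg <- predictLogits(net, x)
  perm <- c(3L, 1L, 4L, 2L)
  net2 <- net
  net2@outDense[[1]]$params$W <- net@outDense[[1]]$params$W[perm, ]
  net2@outDense[[1]]$params$b <- net@outDense[[1]]$params$b[perm]
  expect_equal(predictLogits(net2, x), lg[perm, , drop = FALSE])
})

test_that("gradient reaches every parameter group after one backward pass", {
  net <- buildFusionNetwork(tinyCfg(useLocation = TRUE), seed = 8)
  woundfusion:::withSeed(9, {
    net@outDense[[1]]$params$W[] <- rnorm(length(net@outDense[[1]]$params$W),
                                          0, 0.1)
  })
  x <- array(rnorm(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  loc <- matrix(0, 484, 4); loc[cbind(c(131, 135, 176, 180), 1:4)] <- 1
  fw <- woundfusion:::netForward(net, x, loc, training = TRUE)
  ce <- woundfusion:::nnSoftmaxCrossEntropy(fw$logits, c(1, 2, 3, 4))
  bw <- woundfusion:::netBackward(net, fw$cache, ce$dlogits)
  g <- bw$grads
  groups <- list(backbone1 = g$branches$b1, backbone2 = g$branches$b2,
                 backbone3 = g$branches$b3, aggregation = g$aggregation,
                 dense0 = g$dense0, head = g$head, location = g$gmlp,
                 output = g$outDense)
  for (nm in names(groups))
    expect_gt(woundfusion:::treeSumSq(groups[[nm]]), 0)
})

test_that("parameter counting and description are deterministic", {
  net1 <- buildFusionNetwork(tinyCfg(), seed = 10)
  net2 <- buildFusionNetwork(tinyCfg(), seed = 10)
  expect_identical(countParameters(net1), countParameters(net2))
  expect_identical(describeNetwork(net1), describeNetwork(net2))
  ## summary lists exactly the three backbone branches
  expect_length(grep("^  branch [123]:", describeNetwork(net1)), 3L)
  ## the canonical full-scale configuration is strictly larger
  canon <- buildFusionNetwork(canonicalNetworkConfig(), seed = 1)
  expect_gt(countParameters(canon), countParameters(net1))
})

test_that("checkpoints round-trip parameters and configuration", {
  net <- buildFusionNetwork(tinyCfg(useLocation = TRUE), seed = 11)
  p <- file.path(tempdir(), "ckpt.rds")
  saveNetwork(net, p)
  net2 <- loadNetwork(p)
  expect_identical(woundfusion:::netParams(net2), woundfusion:::netParams(net))
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  bm <- canonicalBodyMap()
  expect_identical(predictLogits(net, x, 135L, bodyMap = bm),
                   predictLogits(net2, x, 135L, bodyMap = bm))
})
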