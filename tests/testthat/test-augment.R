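unitCfg <- function(size = 64L, ...) {
  args <- utils::modifyList(
    list(targetSize = c(size, size), pHflip = 0, pVflip = 0, pRotate = 0,
         pAffine = 0, pNoise = 0, pDropout = 0, normMean = c(0, 0, 0),
         normSd = c(1, 1, 1)),
    list(...))
  do.call(augmentConfig, args)
}

test_that("any input is resized to the configured target", {
  img <- randomImage(40, seed = 1)
  tf <- buildTransform(augmentConfig(targetSize = c(256L, 256L)), TRUE)
  out <- applyTransform(tf, img, seed = 1)
  expect_equal(dim(out), c(256L, 256L, 3L))
  tfe <- buildTransform(augmentConfig(targetSize = c(256L, 256L)), FALSE)
  expect_equal(dim(applyTransform(tfe, img)), c(256L, 256L, 3L))
})

test_that("the all-zero-probability pipeline is the identity", {
  img <- randomImage(64, seed = 2)
  out <- applyTransform(buildTransform(unitCfg(64), TRUE), img, seed = 1)
  expect_equal(as.vector(out), as.vector(img), tolerance = 0)
  expect_length(attr(out, "applied"), 0L)
})

test_that("evaluation transforms never augment", {
  img <- randomImage(64, seed = 3)
  cfgAll <- augmentConfig(targetSize = c(64L, 64L), pHflip = 1, pVflip = 1,
                          pRotate = 1, pAffine = 1, pNoise = 1, pDropout = 1,
                          normMean = c(0, 0, 0), normSd = c(1, 1, 1))
  out <- applyTransform(buildTransform(cfgAll, training = FALSE), img, 5)
  expect_equal(as.vector(out), as.vector(img))
})

test_that("deterministic given the seed; flip of flip restores the image", {
  img <- randomImage(48, seed = 4)
  tf <- buildTransform(augmentConfig(targetSize = c(48L, 48L)), TRUE)
  expect_identical(applyTransform(tf, img, seed = 9),
                   applyTransform(tf, img, seed = 9))
  cfgH <- unitCfg(48, pHflip = 1)
  tfH <- buildTransform(cfgH, TRUE)
  once <- unclass(applyTransform(tfH, img, 1))
  attr(once, "applied") <- NULL
  twice <- applyTransform(tfH, once, 2)
  expect_equal(as.vector(twice), as.vector(img))
})

test_that("Gaussian noise raises the pixel standard deviation to sigma", {
  cfgN <- unitCfg(256, pNoise = 1)
  cfgN@noiseSigma <- 0.05
  flat <- array(0.5, c(64, 64, 3))
  out <- applyTransform(buildTransform(cfgN, TRUE), flat, seed = 6)
  expect_lt(abs(sd(out) - 0.05) / 0.05, 0.1)
})

test_that("coarse dropout removes exactly one axis-aligned rectangle", {
  cfgD <- unitCfg(64, pDropout = 1, dropoutMaxHoles = 1L,
                  holeSize = c(8L, 16L))
  flat <- array(0.5, c(64, 64, 3))
  out <- applyTransform(buildTransform(cfgD, TRUE), flat, seed = 7)
  z <- which(out[, , 1] == cfgD@holeFill, arr.ind = TRUE)
  expect_gt(nrow(z), 0)
  ## the zeroed region is a full rectangle across all channels
  expect_equal(nrow(z), length(unique(z[, 1])) * length(unique(z[, 2])))
  expect_true(all(out[, , 2][z] == cfgD@holeFill))
})

test_that("label-free contract: transforms touch only pixels", {
  ## applyTransform takes and returns image arrays only; labels and
  ## locations live in the manifest and cannot be altered by construction.
  ## Check the output type contract instead.
  img <- randomImage(32, seed = 8)
  out <- applyTransform(buildTransform(augmentConfig(
    targetSize = c(32L, 32L)), TRUE), img, 3)
  expect_true(is.numeric(out) && length(dim(out)) == 3L)
})

test_that("each transform fires at close to its configured probability", {
  img <- randomImage(16, seed = 9)
  cfg <- augmentConfig(targetSize = c(16L, 16L), rotateLimit = 10,
                       holeSize = c(2L, 4L), dropoutMaxHoles = 2L)
  tf <- buildTransform(cfg, TRUE)
  n <- 1000L
  counts <- c(rotate = 0, hflip = 0, vflip = 0, affine = 0, noise = 0,
              dropout = 0)
  woundfusion:::withSeed(123, {
    for (i in seq_len(n)) {
      ap <- attr(applyTransform(tf, img), "applied")
      counts[ap] <- counts[ap] + 1
    }
  })
  rates <- counts / n
  expect_true(all(rates >= 0.45 & rates <= 0.55),
              info = paste(names(rates), round(rates, 3), collapse = ", "))
})

test_that("normalisation applies the configured channel statistics", {
  img <- array(0.5, c(8, 8, 3))
  cfg <- augmentConfig(targetSize = c(8L, 8L))
  out <- applyTransform(buildTransform(cfg, FALSE), img)
  expect_equal(out[1, 1, ], (0.5 - cfg@normMean) / cfg@normSd,
               tolerance = 1e-12)
})

test_that("non-image input produces a decode error", {
  bad <- file.path(tempdir(), "not_an_image.png")
  writeLines("plain text", bad)
  expect_error(loadImage(bad), "cannot decode")
})
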