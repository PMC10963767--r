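## Training-time stochastic augmentation pipeline.
##
## Images are numeric arrays of dim (width, height, 3) on the unit intensity
## scale — the EBImage layout — so EBImage's geometric operations apply
## directly. The training transform is
##   resize -> {rotate, hflip, vflip, affine, Gaussian noise, coarse dropout}
##   each applied with its configured probability -> normalisation;
## the evaluation transform is resize -> normalisation only. Labels and
## locations are never touched by augmentation.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Augmentation configuration
#'
#' Transform names follow the training pipeline: resize, rotation, flips,
#' affine (scale / shift / rotate), Gaussian noise and coarse dropout
#' (random rectangular region removal), each applied with its probability.
#' Magnitudes default to conventional ranges and are fully overridable; the
#' normalisation statistics default to the ImageNet values the pretrained
#' backbones expect.
#'
#' @param targetSize integer(2) output (height, width); default (256, 256).
#' @param pHflip,pVflip,pRotate,pAffine,pNoise,pDropout application
#'   probabilities in `[0, 1]` (default 0.5 each).
#' @param rotateLimit maximum absolute rotation in degrees (default 30).
#' @param affineScale scale range (default 0.9..1.1); `affineShift` maximum
#'   shift fraction of the image side (default 0.1); `affineRotate` maximum
#'   affine rotation in degrees (default 15).
#' @param noiseSigma Gaussian noise standard deviation on the unit scale
#'   (default 0.03).
#' @param dropoutMaxHoles maximum rectangles removed (default 8);
#'   `holeSize` side range in pixels (default 8..32); `holeFill` fill value.
#' @param normMean,normSd per-channel normalisation statistics.
#' @return An [AugmentConfig-class].
#' @export
augmentConfig <- function(targetSize = c(256L, 256L),
                          pHflip = 0.5, pVflip = 0.5, pRotate = 0.5,
                          pAffine = 0.5, pNoise = 0.5, pDropout = 0.5,
                          rotateLimit = 30, affineScale = c(0.9, 1.1),
                          affineShift = 0.1, affineRotate = 15,
                          noiseSigma = 0.03, dropoutMaxHoles = 8L,
                          holeSize = c(8L, 32L), holeFill = 0,
                          normMean = IMAGENET_MEAN, normSd = IMAGENET_SD) {
  methods::new("AugmentConfig",
               targetSize = as.integer(targetSize), pHflip = pHflip,
               pVflip = pVflip, pRotate = pRotate, pAffine = pAffine,
               pNoise = pNoise, pDropout = pDropout, rotateLimit = rotateLimit,
               affineScale = as.numeric(affineScale),
               affineShift = affineShift, affineRotate = affineRotate,
               noiseSigma = noiseSigma,
               dropoutMaxHoles = as.integer(dropoutMaxHoles),
               holeSize = as.integer(holeSize), holeFill = holeFill,
               normMean = as.numeric(normMean), normSd = as.numeric(normSd))
}

#' Build a transform from a configuration
#'
#' @param config An [AugmentConfig-class].
#' @param training TRUE for the stochastic training transform; FALSE for the
#'   deterministic evaluation transform (resize + normalisation only).
#' @return A transform object for [applyTransform()].
#' @export
buildTransform <- function(config, training = TRUE) {
  methods::validObject(config)
  structure(list(config = config, training = isTRUE(training)),
            class = "wfTransform")
}

#' Load an image file
#'
#' Reads PNG/JPEG into a (width, height, 3) array on the unit scale;
#' greyscale images are replicated to 3 channels, alpha is dropped.
#'
#' @param path Image file path.
#' @return Numeric array (W, H, 3).
#' @export
loadImage <- function(path) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Write an image file
#'
#' @param image Numeric array (W, H, 3); values clipped to `[0, 1]`.
#' @param path Output path (format from the extension, e.g. `.png`).
#' @return `path`, invisibly.
#' @export
saveImage <- function(image, path) {
  img <- EBImage::Image(pmin(pmax(image, 0), 1), colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

resizeImage <- function(image, h, w) {
  if (dim(image)[1] == w && dim(image)[2] == h) return(image)
  img <- EBImage::Image(image, colormode = "Color")
  EBImage::imageData(EBImage::resize(img, w = w, h = h))
}

affineMatrix <- function(scale, theta, tx, ty, w, h) {
  L <- scale * matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)),
                      2, 2, byrow = TRUE)
  ctr <- c(w / 2, h / 2)
  tr <- ctr - as.vector(L %*% ctr) + c(tx, ty)
  cbind(c(L[1, 1], L[1, 2], tr[1]), c(L[2, 1], L[2, 2], tr[2]))
}

#' Apply a transform to an image
#'
#' Deterministic given the random state: the same image with the same `seed`
#' always yields the same output. The transforms that fired are recorded in
#' the `"applied"` attribute of the result.
#'
#' @param transform From [buildTransform()].
#' @param image Numeric array (W, H, 3) or an image file path.
#' @param seed Optional integer seed; when NULL the current RNG stream is
#'   consumed.
#' @return Transformed, normalised array of the configured target size.
#' @export
applyTransform <- function(transform, image, seed = NULL) {
  wfAssert(inherits(transform, "wfTransform"), "not a transform object")
  if (is.character(image)) image <- loadImage(image)
  wfAssert(length(dim(image)) == 3L && dim(image)[3] == 3L,
           "expected a 3-channel image")
  cf <- transform$config
  run <- function() {
    h <- cf@targetSize[1]; w <- cf@targetSize[2]
    img <- resizeImage(image, h, w)
    applied <- character(0)
    if (transform$training) {
      if (stats::runif(1) < cf@pRotate) {
        ang <- stats::runif(1, -cf@rotateLimit, cf@rotateLimit)
        img <- EBImage::imageData(EBImage::rotate(
          EBImage::Image(img, colormode = "Color"), ang,
          output.dim = c(w, h), bg.col = "black"))
        applied <- c(applied, "rotate")
      }
      if (stats::runif(1) < cf@pHflip) {
        img <- img[rev(seq_len(w)), , , drop = FALSE]
        applied <- c(applied, "hflip")
      }
      if (stats::runif(1) < cf@pVflip) {
        img <- img[, rev(seq_len(h)), , drop = FALSE]
        applied <- c(applied, "vflip")
      }
      if (stats::runif(1) < cf@pAffine) {
        sc <- stats::runif(1, cf@affineScale[1], cf@affineScale[2])
        th <- stats::runif(1, -cf@affineRotate, cf@affineRotate) * pi / 180
        tx <- stats::runif(1, -cf@affineShift, cf@affineShift) * w
        ty <- stats::runif(1, -cf@affineShift, cf@affineShift) * h
        m <- affineMatrix(sc, th, tx, ty, w, h)
        img <- EBImage::imageData(EBImage::affine(
          EBImage::Image(img, colormode = "Color"), m,
          output.dim = c(w, h), bg.col = "black"))
        applied <- c(applied, "affine")
      }
      if (stats::runif(1) < cf@pNoise) {
        img <- img + array(stats::rnorm(length(img), 0, cf@noiseSigma), dim(img))
        img <- pmin(pmax(img, 0), 1)
        applied <- c(applied, "noise")
      }
      if (stats::runif(1) < cf@pDropout) {
        nHoles <- sample.int(cf@dropoutMaxHoles, 1L)
        for (i in seq_len(nHoles)) {
          hw <- min(w, sample(seq.int(cf@holeSize[1], cf@holeSize[2]), 1L))
          hh <- min(h, sample(seq.int(cf@holeSize[1], cf@holeSize[2]), 1L))
          x0 <- sample.int(w - hw + 1L, 1L)
          y0 <- sample.int(h - hh + 1L, 1L)
          img[x0:(x0 + hw - 1L), y0:(y0 + hh - 1L), ] <- cf@holeFill
        }
        applied <- c(applied, "dropout")
      }
    }
    for (ch in 1:3)
      img[, , ch] <- (img[, , ch] - cf@normMean[ch]) / cf@normSd[ch]
    structure(img, applied = applied)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}
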