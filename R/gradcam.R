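## Gradient-weighted class-activation maps on the convolutional layers of
## the backbone branches: channel weights are the spatial means of the
## target logit's gradient at the layer, the heatmap is the ReLU of the
## weighted activation sum, max-normalised.

## Core arithmetic shared by the engine path and tests: act and grad are
## (H, W, C) arrays for one sample.
camFromActGrad <- function(act, grad) {
  d <- dim(act)
  w <- colMeans(matrix(grad, d[1] * d[2], d[3]))       # per-channel weight
  hm <- matrix(as.vector(matrix(act, d[1] * d[2], d[3]) %*% w), d[1], d[2])
  hm <- pmax(hm, 0)
  mx <- max(hm)
  if (mx > 0) hm <- hm / mx
  hm
}

#' Eligible Grad-CAM layers
#'
#' Identifiers of the convolutional layers in the three backbone branches.
#' The default target of [gradCam()] is each branch's last convolution.
#'
#' @param net A [FusionNetwork-class].
#' @return Character vector of layer ids of the form `"branch<i>:conv<j>"`.
#' @export
camLayers <- function(net) {
  unlist(lapply(1:3, function(i) {
    idx <- topLevelConvIdx(net@branches[[i]]$layers)
    sprintf("branch%d:conv%d", i, idx)
  }))
}

parseLayerId <- function(net, layerId) {
  m <- regmatches(layerId, regexec("^branch([123]):conv([0-9]+)$", layerId))[[1]]
  ok <- length(m) == 3L
  if (ok) {
    br <- as.integer(m[2]); ly <- as.integer(m[3])
    ok <- ly %in% topLevelConvIdx(net@branches[[br]]$layers)
  }
  if (!ok)
    stop("unknown layer '", layerId, "'; eligible layers: ",
         paste(camLayers(net), collapse = ", "), call. = FALSE)
  c(br, ly)
}

#' Gradient-weighted class-activation map
#'
#' Computes the Grad-CAM heatmap for one image at a convolutional layer of
#' one backbone branch: per-channel weights are the spatial means of
#' d logit(target) / d activation, and the heatmap is the rectified,
#' max-normalised weighted sum of the activation channels.
#'
#' @param net A [FusionNetwork-class].
#' @param image A (W, H, 3) image array (already normalised the way the
#'   network expects) or an image file path (then resized + normalised
#'   with the default evaluation transform).
#' @param location Optional location: a one-hot vector, or an integer ID
#'   with `bodyMap` supplied. Required iff the network uses the location
#'   branch.
#' @param targetClass 1-based class index of the logit to explain.
#' @param layerId Layer id from [camLayers()]; default the last
#'   convolution of branch 1.
#' @param bodyMap Optional [BodyMap-class] to encode an integer location.
#' @return A [CamMap-class].
#' @export
gradCam <- function(net, image, location = NULL, targetClass, layerId = NULL,
                    bodyMap = NULL) {
  cf <- net@config
  wfAssert(targetClass >= 1L && targetClass <= cf@numClasses,
           "targetClass must lie in 1..", cf@numClasses)
  if (is.character(image)) {
    tf <- buildTransform(augmentConfig(targetSize = c(cf@imageSize,
                                                      cf@imageSize)), FALSE)
    image <- applyTransform(tf, image)
  }
  if (is.null(layerId)) {
    idx <- topLevelConvIdx(net@branches[[1]]$layers)
    layerId <- sprintf("branch1:conv%d", idx[length(idx)])
  }
  tgt <- parseLayerId(net, layerId)
  x <- asBatch(image)
  loc <- NULL
  if (cf@useLocation) {
    wfAssert(!is.null(location), "this network requires a location")
    if (length(location) == 1L) {
      wfAssert(!is.null(bodyMap), "supply bodyMap to encode an integer location")
      location <- encodeLocation(bodyMap, as.integer(location))
    }
    loc <- matrix(location, ncol = 1)
  }
  ## forward with per-layer outputs kept on the target branch
  branchRun <- seqForward(net@branches[[tgt[1]]]$layers, x, training = FALSE,
                          keepOutputs = TRUE)
  act <- branchRun$outputs[[tgt[2]]]
  fw <- netForward(net, x, loc, training = FALSE)
  dlog <- matrix(0, cf@numClasses, 1)
  dlog[targetClass, 1] <- 1
  ## tap the gradient at the requested layer of the requested branch
  netTap <- net
  netTap@meta$lastConv[[tgt[1]]] <- tgt[2]
  bw <- netBackward(netTap, fw$cache, dlog, wantBranchTaps = TRUE)
  grad <- bw$branchTaps[[tgt[1]]]
  hm <- camFromActGrad(array(act[, , , 1], dim(act)[1:3]),
                       array(grad[, , , 1], dim(grad)[1:3]))
  methods::new("CamMap", heatmap = hm, targetClass = as.integer(targetClass),
               layerId = layerId)
}

#' Grad-CAM at the last convolution of every branch
#'
#' One map per backbone branch, as in per-network interpretability panels.
#'
#' @inheritParams gradCam
#' @return List of three [CamMap-class] objects named by layer id.
#' @export
gradCamAll <- function(net, image, location = NULL, targetClass,
                       bodyMap = NULL) {
  ids <- vapply(1:3, function(i) {
    idx <- topLevelConvIdx(net@branches[[i]]$layers)
    sprintf("branch%d:conv%d", i, idx[length(idx)])
  }, character(1))
  out <- lapply(ids, function(id)
    gradCam(net, image, location, targetClass, id, bodyMap))
  names(out) <- ids
  out
}

## Fixed blue -> green -> yellow -> red colormap (jet-like), deterministic.
camColormap <- function(v) {
  ramp <- grDevices::colorRamp(c("#00007F", "#0000FF", "#00FFFF", "#FFFF00",
                                 "#FF0000"))
  ramp(pmin(pmax(v, 0), 1)) / 255
}

#' Overlay a class-activation map on an image
#'
#' Upsamples the heatmap bilinearly to the image size, maps it through a
#' fixed colormap and alpha-blends it over the image; the result is written
#' as a PNG. Output bytes are deterministic for fixed inputs.
#'
#' @param image A (W, H, 3) unit-scale image array or an image file path.
#' @param cam A [CamMap-class].
#' @param outPath Output PNG path.
#' @param alpha Blend weight of the heatmap (default 0.5); positions where
#'   the heatmap is zero keep the base image.
#' @return `outPath`, invisibly.
#' @export
overlayCam <- function(image, cam, outPath, alpha = 0.5) {
  if (is.character(image)) image <- loadImage(image)
  w <- dim(image)[1]; h <- dim(image)[2]
  hm <- camHeatmap(cam)
  ## heatmap is (h', w') in row = height convention; transpose into the
  ## image (width, height) layout before resizing
  hmImg <- EBImage::resize(EBImage::Image(t(hm)), w = w, h = h)
  hv <- as.vector(EBImage::imageData(hmImg))
  colv <- camColormap(hv)
  out <- image
  a <- alpha * pmin(pmax(hv, 0), 1)
  for (ch in 1:3)
    out[, , ch] <- (1 - a) * image[, , ch] + a * colv[, ch]
  saveImage(out, outPath)
  invisible(outPath)
}
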