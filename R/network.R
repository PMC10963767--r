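## Assembly of the full multi-modal architecture: three truncated backbones
## in parallel, spatial alignment and channel concatenation, an aggregation
## stack of ConvBlock + P_scSE + dropout repeats, a flattening dense layer,
## a dense head interleaved with axial attention, the optional adaptive-
## gated MLP location branch, and the output layer mapping to K logits.

#' Fusion-network configuration
#'
#' @param backbones character(3) backbone names; the canonical configuration
#'   is `c("resnet152", "vgg16", "efficientnet_b2")`, the desk-scale default
#'   `c("tiny_a", "tiny_b", "tiny_c")`.
#' @param recipes character(3) truncation recipe ids (`""` = default).
#' @param pretrained logical(3); see [buildBackbone()].
#' @param fusionChannels Channels of the aggregation ConvBlocks.
#' @param aggregationRepeats ConvBlock + P_scSE + dropout repeats (default 2).
#' @param headWidths integer(2) widths of the two dense head layers.
#' @param gmlpHidden,gmlpOut Location-branch hidden and output widths.
#' @param dropout Dropout rate in the custom layers (default 0.3).
#' @param useLocation Enable the location branch.
#' @param locationDim Length of the location one-hot (484 canonical).
#' @param numClasses Number of output classes K.
#' @param imageSize Square input side in pixels.
#' @param mergeMode P_scSE merge: `"maxout_add"` (default), `"max"`, `"add"`.
#' @param seReduction Squeeze-and-excitation reduction ratio (default 16).
#' @return A [NetworkConfig-class].
#' @export
networkConfig <- function(backbones = c("tiny_a", "tiny_b", "tiny_c"),
                          recipes = c("", "", ""),
                          pretrained = c(FALSE, FALSE, FALSE),
                          fusionChannels = 24L, aggregationRepeats = 2L,
                          headWidths = c(64L, 64L), gmlpHidden = 128L,
                          gmlpOut = 32L, dropout = 0.3, useLocation = FALSE,
                          locationDim = 484L, numClasses = 6L,
                          imageSize = 32L, mergeMode = "maxout_add",
                          seReduction = 16L) {
  methods::new("NetworkConfig", backbones = backbones, recipes = recipes,
               pretrained = pretrained,
               fusionChannels = as.integer(fusionChannels),
               aggregationRepeats = as.integer(aggregationRepeats),
               headWidths = as.integer(headWidths),
               gmlpHidden = as.integer(gmlpHidden),
               gmlpOut = as.integer(gmlpOut), dropout = dropout,
               useLocation = isTRUE(useLocation),
               locationDim = as.integer(locationDim),
               numClasses = as.integer(numClasses),
               imageSize = as.integer(imageSize), mergeMode = mergeMode,
               seReduction = as.integer(seReduction))
}

#' Canonical full-scale configuration
#'
#' The three-backbone configuration at 256x256 input.
#'
#' @param ... Overrides passed to [networkConfig()].
#' @export
canonicalNetworkConfig <- function(...) {
  args <- list(backbones = c("resnet152", "vgg16", "efficientnet_b2"),
               fusionChannels = 64L, imageSize = 256L)
  args <- utils::modifyList(args, list(...))
  do.call(networkConfig, args)
}

#' Build a fusion network
#'
#' Assembles the three backbone branches, infers their output grids for the
#' given image size, aligns them by adaptive average pooling to the smallest
#' branch grid, and constructs the aggregation stack, dense head, optional
#' location branch and output layer. All parameters are seeded.
#'
#' @param config A [NetworkConfig-class].
#' @param seed Integer seed for parameter initialisation.
#' @return A [FusionNetwork-class].
#' @export
buildFusionNetwork <- function(config, seed = 1L) {
  methods::validObject(config)
  cf <- config
  branches <- lapply(1:3, function(i)
    buildBackbone(cf@backbones[i], cf@recipes[i], cf@pretrained[i],
                  seed = seed + i))
  inShape <- c(cf@imageSize, cf@imageSize, 3L)
  shapes <- lapply(branches, function(b) shapeInfer(b$layers, inShape))
  grid <- c(min(vapply(shapes, `[`, numeric(1), 1)),
            min(vapply(shapes, `[`, numeric(1), 2)))
  concatC <- sum(vapply(branches, function(b) b$outC, integer(1)))
  net <- withSeed(seed, {
    agg <- list()
    inC <- concatC
    for (rep in seq_len(cf@aggregationRepeats)) {
      agg <- c(agg, list(mkConv(inC, cf@fusionChannels, 3L), mkRelu(),
                         mkPscse(cf@fusionChannels, cf@seReduction,
                                 cf@mergeMode),
                         mkDropout(cf@dropout)))
      inC <- cf@fusionChannels
    }
    flatF <- as.integer(grid[1] * grid[2] * cf@fusionChannels)
    dense0 <- list(mkDense(flatF, cf@headWidths[1]), mkRelu())
    ## layer normalisation in front of each attention keeps its inputs on
    ## a stable scale (the standard companion of residual attention)
    head <- list(mkDense(cf@headWidths[1], cf@headWidths[1]),
                 mkLN(cf@headWidths[1]),
                 mkVattn(cf@headWidths[1]), mkRelu(), mkDropout(cf@dropout),
                 mkDense(cf@headWidths[1], cf@headWidths[2]),
                 mkLN(cf@headWidths[2]),
                 mkVattn(cf@headWidths[2]), mkRelu(), mkDropout(cf@dropout))
    gmlp <- if (cf@useLocation)
      gatedMLPParams(cf@locationDim, cf@gmlpHidden, cf@gmlpOut,
                     seed = seed + 11L) else list()
    outIn <- cf@headWidths[2] + if (cf@useLocation) cf@gmlpOut else 0L
    outDense <- mkDense(outIn, cf@numClasses)
    ## zero-initialised output layer: initial logits are 0, the initial
    ## loss is exactly log(K), and early optimisation is stable
    outDense$params$W[] <- 0
    list(agg = agg, dense0 = dense0, head = head, gmlp = gmlp,
         outDense = outDense, flatF = flatF)
  })
  lastConv <- lapply(branches, function(b) {
    idx <- topLevelConvIdx(b$layers)
    idx[length(idx)]
  })
  methods::new("FusionNetwork", config = cf, branches = branches,
               aggregation = net$agg, dense0 = net$dense0, head = net$head,
               gmlp = net$gmlp, outDense = list(net$outDense),
               meta = list(grid = grid, flattenF = net$flatF,
                           branchShapes = shapes, lastConv = lastConv))
}

## --- forward / backward -----------------------------------------------------

## x: (H, W, 3, N); loc: (locationDim, N) or NULL.
netForward <- function(net, x, loc = NULL, training = FALSE) {
  cf <- net@config
  wfAssert(!cf@useLocation || !is.null(loc),
           "this network uses the location branch; supply `loc`")
  grid <- net@meta$grid
  bOut <- vector("list", 3L)
  bCache <- vector("list", 3L)
  pCache <- vector("list", 3L)
  pooled <- vector("list", 3L)
  branches <- net@branches
  for (i in 1:3) {
    r <- seqForward(branches[[i]]$layers, x, training)
    branches[[i]]$layers <- r$layers
    bOut[[i]] <- r$y
    bCache[[i]] <- r$caches
    p <- nnAdaptiveAvgPoolForward(r$y, grid[1], grid[2])
    pooled[[i]] <- p$y
    pCache[[i]] <- p$cache
  }
  N <- dim(x)[4]
  chans <- vapply(pooled, function(p) dim(p)[3], numeric(1))
  cat3 <- array(0, c(grid[1], grid[2], sum(chans), N))
  off <- 0L
  for (i in 1:3) {
    cat3[, , off + seq_len(chans[i]), ] <- pooled[[i]]
    off <- off + chans[i]
  }
  ar <- seqForward(net@aggregation, cat3, training)
  flat <- ar$y
  dim(flat) <- c(prod(dim(ar$y)[1:3]), N)
  d0 <- seqForward(net@dense0, flat, training)
  hd <- seqForward(net@head, d0$y, training)
  feats <- hd$y
  gCache <- NULL
  if (cf@useLocation) {
    g <- wfGmlpFwd(loc, net@gmlp)
    gCache <- g$cache
    feats <- rbind(feats, g$y)
  }
  od <- layerForward(net@outDense[[1]], feats, training)
  list(logits = od$y,
       net = { net@branches <- branches
               net@aggregation <- ar$layers
               net },
       cache = list(bCache = bCache, pCache = pCache, chans = chans,
                    aggCache = ar$caches, aggDim = dim(ar$y),
                    d0Cache = d0$caches, hdCache = hd$caches,
                    gCache = gCache, odCache = od$cache,
                    headWidth = cf@headWidths[2]))
}

## dlogits: (K, N). Returns grads tree aligned with netParams(net), plus the
## gradient and activation at each branch's last convolution (Grad-CAM).
netBackward <- function(net, cache, dlogits, wantBranchTaps = FALSE) {
  cf <- net@config
  od <- layerBackward(net@outDense[[1]], cache$odCache, dlogits)
  dfeats <- od$dx
  gGrads <- list()
  if (cf@useLocation) {
    hw <- cache$headWidth
    dHead <- dfeats[seq_len(hw), , drop = FALSE]
    dG <- dfeats[hw + seq_len(nrow(dfeats) - hw), , drop = FALSE]
    gb <- wfGmlpBwd(cache$gCache, dG, net@gmlp)
    gGrads <- gb$grads
  } else {
    dHead <- dfeats
  }
  hb <- seqBackward(net@head, cache$hdCache, dHead)
  d0b <- seqBackward(net@dense0, cache$d0Cache, hb$dx)
  dflat <- d0b$dx
  dim(dflat) <- cache$aggDim
  ab <- seqBackward(net@aggregation, cache$aggCache, dflat)
  dcat <- ab$dx
  off <- 0L
  branchGrads <- vector("list", 3L)
  taps <- if (wantBranchTaps) vector("list", 3L) else NULL
  for (i in 1:3) {
    dpool <- dcat[, , off + seq_len(cache$chans[i]), , drop = FALSE]
    off <- off + cache$chans[i]
    dpb <- nnAdaptiveAvgPoolBackward(cache$pCache[[i]], dpool)
    want <- if (wantBranchTaps) net@meta$lastConv[[i]] else integer(0)
    sb <- seqBackward(net@branches[[i]]$layers, cache$bCache[[i]], dpb$dx,
                      wantDyAt = want)
    branchGrads[[i]] <- sb$grads
    if (wantBranchTaps)
      taps[[i]] <- sb$dyAt[[as.character(net@meta$lastConv[[i]])]]
  }
  names(branchGrads) <- paste0("b", 1:3)
  grads <- list(branches = branchGrads, aggregation = ab$grads,
                dense0 = d0b$grads, head = hb$grads)
  if (cf@useLocation) grads$gmlp <- gGrads
  grads$outDense <- list(l1 = od$grads)
  list(grads = grads, branchTaps = taps)
}

netParams <- function(net) {
  p <- list(branches = stats::setNames(
              lapply(net@branches, function(b) seqParams(b$layers)),
              paste0("b", 1:3)),
            aggregation = seqParams(net@aggregation),
            dense0 = seqParams(net@dense0),
            head = seqParams(net@head))
  if (net@config@useLocation) p$gmlp <- net@gmlp
  p$outDense <- list(l1 = net@outDense[[1]]$params)
  p
}

netSetParams <- function(net, p) {
  for (i in 1:3)
    net@branches[[i]]$layers <- seqSetParams(net@branches[[i]]$layers,
                                             p$branches[[i]])
  net@aggregation <- seqSetParams(net@aggregation, p$aggregation)
  net@dense0 <- seqSetParams(net@dense0, p$dense0)
  net@head <- seqSetParams(net@head, p$head)
  if (net@config@useLocation) net@gmlp <- p$gmlp
  net@outDense[[1]]$params <- p$outDense$l1
  net
}

## --- user-facing inference --------------------------------------------------

## Accept a (H,W,3,N) batch, a single (W,H,3) image array, or a list of
## (W,H,3) image arrays; images are in the EBImage (width, height, channel)
## layout and are converted to the internal (H,W,C,N) layout.
asBatch <- function(images) {
  if (is.list(images)) {
    arrs <- lapply(images, function(im) aperm(im, c(2, 1, 3)))
    d <- dim(arrs[[1]])
    out <- array(0, c(d, length(arrs)))
    for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
    out
  } else if (length(dim(images)) == 3L) {
    im <- aperm(images, c(2, 1, 3))
    array(im, c(dim(im), 1L))
  } else images
}

#' Network forward pass
#'
#' Computes class logits for a batch of images (plus location encodings when
#' the location branch is enabled). Inference mode: dropout disabled,
#' deterministic.
#'
#' @param net A [FusionNetwork-class].
#' @param images A (H, W, 3, N) batch array, a single (W, H, 3) image, or a
#'   list of images.
#' @param locations One-hot matrix (locationDim, N) — e.g. from
#'   [alignLocations()] — or integer location IDs with `bodyMap` supplied.
#'   Required iff the network was built with `useLocation = TRUE`.
#' @param bodyMap Optional [BodyMap-class] used to encode integer
#'   `locations`.
#' @return Matrix of logits (K, N).
#' @export
predictLogits <- function(net, images, locations = NULL, bodyMap = NULL) {
  x <- asBatch(images)
  cf <- net@config
  if (cf@useLocation) {
    wfAssert(!is.null(locations),
             "network built with useLocation = TRUE: locations are required")
    if (!is.matrix(locations)) {
      wfAssert(!is.null(bodyMap), "supply bodyMap to encode integer locations")
      locations <- vapply(as.integer(locations),
                          function(id) encodeLocation(bodyMap, id),
                          numeric(bodyMapSize(bodyMap)))
      locations <- matrix(locations, ncol = dim(x)[4])
    }
  } else {
    locations <- NULL
  }
  netForward(net, x, locations, training = FALSE)$logits
}

#' @describeIn FusionNetwork Total number of trainable parameters.
#' @export
setMethod("countParameters", "FusionNetwork",
          function(x) as.integer(treeCount(netParams(x))))

#' Describe a network architecture
#'
#' Deterministic text summary: the three backbone branches with their
#' truncation recipes and inferred output shapes for the configured image
#' size, the aggregation stack, head widths, location branch and parameter
#' count.
#'
#' @param net A [FusionNetwork-class].
#' @return Character vector of summary lines.
#' @export
describeNetwork <- function(net) {
  cf <- net@config
  lines <- c(sprintf("FusionNetwork: %d classes, input %dx%dx3, location branch %s",
                     cf@numClasses, cf@imageSize, cf@imageSize,
                     if (cf@useLocation) "ON" else "off"))
  for (i in 1:3) {
    s <- net@meta$branchShapes[[i]]
    lines <- c(lines, sprintf("  branch %d: %s [%s] -> %dx%dx%d", i,
                              net@branches[[i]]$name, net@branches[[i]]$recipe,
                              s[1], s[2], s[3]))
  }
  lines <- c(lines,
    sprintf("  align: adaptive average pool to %dx%d, concat %d channels",
            net@meta$grid[1], net@meta$grid[2],
            sum(vapply(net@branches, function(b) b$outC, integer(1)))),
    sprintf("  aggregation: %d x [ConvBlock(%d) + P_scSE(%s) + dropout %.2f]",
            cf@aggregationRepeats, cf@fusionChannels, cf@mergeMode,
            cf@dropout),
    sprintf("  head: flatten %d -> dense %d -> [dense+axial attention] -> %d",
            net@meta$flattenF, cf@headWidths[1], cf@headWidths[2]))
  if (cf@useLocation)
    lines <- c(lines, sprintf("  location: one-hot %d -> adaptive-gated MLP -> %d",
                              cf@locationDim, cf@gmlpOut))
  c(lines, sprintf("  output: dense -> %d logits | %d parameters",
                   cf@numClasses, countParameters(net)))
}

#' Save / load a network checkpoint
#'
#' Round-trips all parameters and the configuration.
#'
#' @param net A [FusionNetwork-class].
#' @param path Checkpoint file path (RDS).
#' @return `path` invisibly; `loadNetwork` returns the network.
#' @export
saveNetwork <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  net <- readRDS(path)
  wfAssert(methods::is(net, "FusionNetwork"), "not a FusionNetwork checkpoint")
  methods::validObject(net)
  net
}
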