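## Truncated backbone feature extractors.
##
## The three full-scale backbones (ResNet152, VGG16, EfficientNet-B2) are
## cut to mid-depth feature extractors by named, versioned truncation
## recipes; the exact module indices each recipe removes are pinned here so
## the cut is reproducible and falsifiable. The tiny_* backbones are small
## conv stacks of the same structural kind, first-class citizens used for
## CPU-scale experiments and testing.

.RECIPES <- list(
  vgg16 = list(
    id = "vgg16-drop12-v1",
    note = paste("VGG16 counted as 13 conv, 5 pool and 3 FC layers (21);",
                 "the last 12 are dropped, keeping conv1_1..conv3_3 so the",
                 "branch yields an early, primitive-pattern feature map",
                 "(256 channels at 1/4 resolution).")),
  resnet152 = list(
    id = "resnet152-midcut-v1",
    note = paste("Average pooling and the FC layer removed; stage 2 is cut",
                 "inside its third bottleneck, whose last two modules (the",
                 "expanding 1x1 convolution and its batch norm) are removed,",
                 "and all later stages are dropped (128 channels at 1/8",
                 "resolution).")),
  efficientnet_b2 = list(
    id = "efficientnet_b2-dropclassifier-v1",
    note = paste("The final classification layer is removed; the stem, all",
                 "MBConv stages and the 1x1 head convolution are kept (1408",
                 "channels at 1/32 resolution).")),
  tiny_a = list(id = "tiny-v1", note = "two 3x3 conv stages, 8 channels"),
  tiny_b = list(id = "tiny-v1", note = "5x5 then 3x3 conv stages, 12 channels"),
  tiny_c = list(id = "tiny-v1", note = "two 3x3 conv stages, 16 channels"))

#' Backbone truncation recipes
#'
#' The recipe table pinning how each backbone is truncated to a mid-depth
#' feature extractor, and which layer serves as its last convolution for
#' Grad-CAM.
#'
#' @return data.frame with columns `name`, `recipe`, `description`.
#' @export
backboneRecipes <- function() {
  data.frame(name = names(.RECIPES),
             recipe = vapply(.RECIPES, `[[`, character(1), "id"),
             description = vapply(.RECIPES, `[[`, character(1), "note"),
             row.names = NULL)
}

## ResNet bottleneck: 1x1 reduce, 3x3 (carries the stride), 1x1 expand.
mkBottleneck <- function(inC, midC, outC, stride = 1L) {
  main <- list(mkConv(inC, midC, 1L, 1L, 0L), mkBN(midC), mkRelu(),
               mkConv(midC, midC, 3L, stride, "same"), mkBN(midC), mkRelu(),
               mkConv(midC, outC, 1L, 1L, 0L), mkBN(outC))
  down <- if (stride != 1L || inC != outC)
    list(mkConv(inC, outC, 1L, stride, 0L), mkBN(outC)) else NULL
  mkRes(main, down, finalRelu = TRUE)
}

## EfficientNet MBConv block.
mkMBConv <- function(inC, outC, expand, k, stride) {
  expC <- inC * expand
  main <- list()
  if (expand != 1L)
    main <- c(main, list(mkConv(inC, expC, 1L, 1L, 0L), mkBN(expC), mkSwish()))
  main <- c(main, list(mkDwConv(expC, k, stride), mkBN(expC), mkSwish(),
                       mkSE(expC, max(1L, round(inC * 0.25))),
                       mkConv(expC, outC, 1L, 1L, 0L), mkBN(outC)))
  if (stride == 1L && inC == outC) mkRes(main, NULL, finalRelu = FALSE)
  else list(type = "seqflat", main = main)
}

flattenBlocks <- function(blocks) {
  out <- list()
  for (b in blocks) {
    if (!is.null(b$type) && b$type == "seqflat") out <- c(out, b$main)
    else out <- c(out, list(b))
  }
  out
}

backboneLayers <- function(name) {
  switch(name,
    tiny_a = list(layers = list(mkConv(3L, 8L, 3L), mkBN(8L), mkRelu(),
                                mkAvgPool(2L),
                                mkConv(8L, 8L, 3L), mkBN(8L), mkRelu(),
                                mkAvgPool(2L)),
                  outC = 8L),
    tiny_b = list(layers = list(mkConv(3L, 6L, 5L), mkBN(6L), mkRelu(),
                                mkAvgPool(2L),
                                mkConv(6L, 12L, 3L), mkBN(12L), mkRelu(),
                                mkAvgPool(2L)),
                  outC = 12L),
    tiny_c = list(layers = list(mkConv(3L, 8L, 3L), mkBN(8L), mkRelu(),
                                mkAvgPool(2L),
                                mkConv(8L, 16L, 3L), mkBN(16L), mkRelu(),
                                mkAvgPool(2L)),
                  outC = 16L),
    vgg16 = list(layers = list(
      mkConv(3L, 64L, 3L), mkRelu(), mkConv(64L, 64L, 3L), mkRelu(),
      mkMaxPool(2L),
      mkConv(64L, 128L, 3L), mkRelu(), mkConv(128L, 128L, 3L), mkRelu(),
      mkMaxPool(2L),
      mkConv(128L, 256L, 3L), mkRelu(), mkConv(256L, 256L, 3L), mkRelu(),
      mkConv(256L, 256L, 3L), mkRelu()), outC = 256L),
    resnet152 = {
      layers <- list(mkConv(3L, 64L, 7L, 2L, 3L), mkBN(64L), mkRelu(),
                     mkMaxPool(3L, 2L, 1L),
                     mkBottleneck(64L, 64L, 256L, 1L),
                     mkBottleneck(256L, 64L, 256L, 1L),
                     mkBottleneck(256L, 64L, 256L, 1L),
                     mkBottleneck(256L, 128L, 512L, 2L),
                     mkBottleneck(512L, 128L, 512L, 1L),
                     ## third block of stage 2, its last two modules removed:
                     mkConv(512L, 128L, 1L, 1L, 0L), mkBN(128L), mkRelu(),
                     mkConv(128L, 128L, 3L, 1L, "same"), mkBN(128L), mkRelu())
      list(layers = layers, outC = 128L)
    },
    efficientnet_b2 = {
      stages <- list(c(1, 3, 1, 16, 2), c(6, 3, 2, 24, 3), c(6, 5, 2, 48, 3),
                     c(6, 3, 2, 88, 4), c(6, 5, 1, 120, 4), c(6, 5, 2, 208, 5),
                     c(6, 3, 1, 352, 2))
      blocks <- list()
      inC <- 32L
      for (st in stages) {
        expand <- as.integer(st[1]); k <- as.integer(st[2])
        s <- as.integer(st[3]); outC <- as.integer(st[4])
        reps <- as.integer(st[5])
        for (rr in seq_len(reps)) {
          blocks <- c(blocks, list(mkMBConv(inC, outC, expand, k,
                                            if (rr == 1L) s else 1L)))
          inC <- outC
        }
      }
      layers <- c(list(mkConv(3L, 32L, 3L, 2L, "same"), mkBN(32L), mkSwish()),
                  flattenBlocks(blocks),
                  list(mkConv(352L, 1408L, 1L, 1L, 0L), mkBN(1408L),
                       mkSwish()))
      list(layers = layers, outC = 1408L)
    },
    stop("unknown backbone: ", name, " (available: ",
         paste(names(.RECIPES), collapse = ", "), ")"))
}

#' Build a (truncated) backbone feature extractor
#'
#' Returns the truncated network mapping a (3, H, W) image batch to a
#' mid-depth feature map, with parameters randomly initialised
#' (`pretrained = FALSE`, the tested path) or loaded from a user-supplied
#' parameter file (`pretrained = TRUE` with `weightsFile`; pretrained
#' weights are not bundled).
#'
#' @param name One of resnet152, vgg16, efficientnet_b2, tiny_a, tiny_b,
#'   tiny_c.
#' @param recipe Truncation recipe id; `NULL` selects the backbone's default
#'   (see [backboneRecipes()]). An unknown id is an error listing the
#'   available recipes.
#' @param pretrained Load pretrained weights from `weightsFile`.
#' @param weightsFile RDS file holding a parameter tree matching the
#'   architecture (required when `pretrained = TRUE`).
#' @param seed Integer seed for random initialisation.
#' @return A backbone object (layers + metadata) usable in a fusion network.
#' @export
buildBackbone <- function(name, recipe = NULL, pretrained = FALSE,
                          weightsFile = NULL, seed = 1L) {
  wfAssert(name %in% names(.RECIPES), "unknown backbone: ", name,
           " (available: ", paste(names(.RECIPES), collapse = ", "), ")")
  default <- .RECIPES[[name]]$id
  if (is.null(recipe) || identical(recipe, "")) recipe <- default
  if (!identical(recipe, default))
    stop("unknown recipe '", recipe, "' for ", name,
         " (available: ", default, ")", call. = FALSE)
  bb <- withSeed(seed, backboneLayers(name))
  if (pretrained) {
    if (is.null(weightsFile) || !file.exists(weightsFile %||% ""))
      stop("pretrained = TRUE requires a weightsFile with a saved parameter ",
           "tree; pretrained weights are not bundled with the package",
           call. = FALSE)
    bb$layers <- seqSetParams(bb$layers, readRDS(weightsFile))
  }
  structure(list(name = name, recipe = recipe, layers = bb$layers,
                 outC = bb$outC), class = "wfBackbone")
}
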