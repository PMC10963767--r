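## S4 classes for the central data objects. Constructors with argument
## checking live in the module files; validity methods here enforce the
## structural invariants.

#' BodyMap: the anatomical location vocabulary
#'
#' Maps integer body-map region IDs to anatomical names and to one-hot
#' positions. The canonical map (shipped with the package) has 484 regions;
#' user-supplied vocabularies may be smaller or non-contiguous, in which case
#' the one-hot position of an ID is its rank in ascending ID order.
#'
#' @slot entries data.frame with columns `location_id` (integer) and `name`
#'   (character); IDs unique and within 1..484.
#' @export
setClass("BodyMap", representation(entries = "data.frame"),
  validity = function(object) {
    e <- object@entries
    if (!all(c("location_id", "name") %in% names(e)))
      return("entries must have columns location_id and name")
    if (anyDuplicated(e$location_id)) {
      dup <- unique(e$location_id[duplicated(e$location_id)])
      return(paste0("duplicate location_id: ", paste(dup, collapse = ", ")))
    }
    if (nrow(e) && (min(e$location_id) < 1L || max(e$location_id) > 484L))
      return("location_id values must lie in 1..484")
    TRUE
  })

#' WoundManifest: the dataset model
#'
#' An ordered collection of sample records (image reference, class label,
#' optional body-map location ID, wound-group ID) together with the ordered
#' class vocabulary.
#'
#' @slot records data.frame with columns `image`, `label`, `location_id`,
#'   `group_id`.
#' @slot classes character vector; every record label must belong to it.
#' @export
setClass("WoundManifest",
  representation(records = "data.frame", classes = "character"),
  validity = function(object) {
    r <- object@records
    need <- c("image", "label", "location_id", "group_id")
    if (!all(need %in% names(r)))
      return(paste("records must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(object@classes))
      return("class vocabulary contains duplicates")
    if (nrow(r)) {
      bad <- setdiff(unique(r$label), object@classes)
      if (length(bad))
        return(paste0("labels not in class vocabulary: ",
                      paste(bad, collapse = ", "),
                      " (allowed: ", paste(object@classes, collapse = ", "), ")"))
      if (any(!nzchar(r$image))) return("empty image reference")
    }
    TRUE
  })

#' SplitSpec: train/validation/test split specification
#'
#' @slot fractions numeric(3): train, validation, test fractions summing to 1.
#' @slot seed integer seed for the per-class shuffle.
#' @slot groupAware logical; keep records sharing a group_id in one subset.
#' @export
setClass("SplitSpec",
  representation(fractions = "numeric", seed = "integer",
                 groupAware = "logical"),
  validity = function(object) {
    f <- object@fractions
    if (length(f) != 3L) return("fractions must have length 3")
    if (any(f < 0)) return("fractions must be non-negative")
    if (abs(sum(f) - 1) > 1e-9) return("fractions must sum to 1")
    TRUE
  })

#' DatasetSplit: three disjoint manifests
#'
#' @slot train,val,test WoundManifest subsets forming a partition of the
#'   input manifest's records.
#' @slot metadata list with the seed, fractions and achieved per-class counts.
#' @export
setClass("DatasetSplit",
  representation(train = "WoundManifest", val = "WoundManifest",
                 test = "WoundManifest", metadata = "list"),
  validity = function(object) {
    cl <- classLabels(object@train)
    if (!identical(cl, classLabels(object@val)) ||
        !identical(cl, classLabels(object@test)))
      return("subsets carry different class vocabularies")
    TRUE
  })

#' SyntheticSpec: synthetic dataset description
#'
#' @slot classes ordered subset of BG, N, D, P, S, V (at least 2).
#' @slot perClassN samples per class.
#' @slot imageSize square image side in pixels.
#' @slot locationAssoc probability in [0,1] that a wound sample's location is
#'   drawn from its class-preferred region set rather than uniformly.
#' @slot groupsPerClass number of wound groups per class.
#' @slot ambiguousPair character(0), or two class symbols that share one
#'   image appearance (making location the only separating signal).
#' @slot seed integer seed.
#' @export
setClass("SyntheticSpec",
  representation(classes = "character", perClassN = "integer",
                 imageSize = "integer", locationAssoc = "numeric",
                 groupsPerClass = "integer", ambiguousPair = "character",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@classes) < 2L) return("need at least 2 classes")
    bad <- setdiff(object@classes, CLASS_SYMBOLS)
    if (length(bad)) return(paste("unknown classes:", paste(bad, collapse = ", ")))
    if (object@perClassN < 1L) return("perClassN must be >= 1")
    if (object@locationAssoc < 0 || object@locationAssoc > 1)
      return("locationAssoc must lie in [0,1]")
    if (length(object@ambiguousPair) %in% c(0L, 2L) == FALSE)
      return("ambiguousPair must be empty or exactly two classes")
    TRUE
  })

#' AugmentConfig: training-time augmentation settings
#'
#' Probabilities and magnitudes of the stochastic transforms applied to
#' training images (evaluation images get resize + normalisation only).
#'
#' @slot targetSize integer(2): output (height, width), default (256, 256).
#' @slot pHflip,pVflip,pRotate,pAffine,pNoise,pDropout per-transform
#'   application probabilities in [0,1].
#' @slot rotateLimit maximum absolute rotation (degrees).
#' @slot affineScale numeric(2) scale range; affineShift maximum shift as a
#'   fraction of the image side; affineRotate maximum affine rotation
#'   (degrees).
#' @slot noiseSigma Gaussian noise standard deviation on the unit intensity
#'   scale.
#' @slot dropoutMaxHoles maximum number of coarse-dropout rectangles;
#'   holeSize integer(2) side range in pixels; holeFill fill intensity.
#' @slot normMean,normSd per-channel normalisation statistics (defaults are
#'   the ImageNet statistics the pretrained backbones expect).
#' @export
setClass("AugmentConfig",
  representation(targetSize = "integer", pHflip = "numeric", pVflip = "numeric",
                 pRotate = "numeric", pAffine = "numeric", pNoise = "numeric",
                 pDropout = "numeric", rotateLimit = "numeric",
                 affineScale = "numeric", affineShift = "numeric",
                 affineRotate = "numeric", noiseSigma = "numeric",
                 dropoutMaxHoles = "integer", holeSize = "integer",
                 holeFill = "numeric", normMean = "numeric", normSd = "numeric"),
  validity = function(object) {
    pr <- c(object@pHflip, object@pVflip, object@pRotate, object@pAffine,
            object@pNoise, object@pDropout)
    if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0,1]")
    if (any(object@targetSize < 1L)) return("targetSize must be positive")
    if (length(object@affineScale) != 2L) return("affineScale must be a range")
    TRUE
  })

#' NetworkConfig: fusion-network architecture settings
#'
#' @slot backbones character(3): backbone names (resnet152, vgg16,
#'   efficientnet_b2, tiny_a, tiny_b, tiny_c).
#' @slot recipes character(3): truncation recipe ids (see
#'   [backboneRecipes()]); `""` selects each backbone's default.
#' @slot pretrained logical(3); TRUE requires user-supplied weight files.
#' @slot fusionChannels channels of the aggregation ConvBlocks.
#' @slot aggregationRepeats number of ConvBlock + P_scSE + dropout repeats.
#' @slot headWidths integer(2): widths of the two dense head layers.
#' @slot gmlpHidden,gmlpOut hidden and output widths of the location branch.
#' @slot dropout dropout rate in custom layers.
#' @slot useLocation enable the adaptive-gated MLP location branch.
#' @slot locationDim length of the location one-hot (484 canonical).
#' @slot numClasses number of output classes K.
#' @slot imageSize square input image side.
#' @slot mergeMode P_scSE merge: maxout_add, max, or add.
#' @slot seReduction squeeze-and-excitation reduction ratio r.
#' @export
setClass("NetworkConfig",
  representation(backbones = "character", recipes = "character",
                 pretrained = "logical", fusionChannels = "integer",
                 aggregationRepeats = "integer", headWidths = "integer",
                 gmlpHidden = "integer", gmlpOut = "integer",
                 dropout = "numeric", useLocation = "logical",
                 locationDim = "integer", numClasses = "integer",
                 imageSize = "integer", mergeMode = "character",
                 seReduction = "integer"),
  validity = function(object) {
    if (length(object@backbones) != 3L)
      return("the canonical configuration has exactly 3 backbones")
    if (object@numClasses < 2L) return("numClasses must be >= 2")
    if (length(object@headWidths) != 2L) return("headWidths must have length 2")
    if (!object@mergeMode %in% c("maxout_add", "max", "add"))
      return("mergeMode must be maxout_add, max or add")
    TRUE
  })

#' FusionNetwork: the assembled three-branch architecture
#'
#' Built by [buildFusionNetwork()]. Parameters live in nested lists of
#' numeric arrays; use [predictLogits()] for inference, [trainNetwork()] for
#' fitting and [countParameters()] / [describeNetwork()] for inspection.
#'
#' @slot config the [NetworkConfig-class] used to build the network.
#' @slot branches list of three backbone layer stacks.
#' @slot aggregation aggregation stack (ConvBlock + P_scSE + dropout repeats).
#' @slot dense0 dense layer after flattening.
#' @slot head dense head interleaved with axial attention.
#' @slot gmlp adaptive-gated MLP parameters (empty list when the location
#'   branch is disabled).
#' @slot outDense final dense layer mapping to K logits.
#' @slot meta cached shape information (alignment grid, flatten width,
#'   last-convolution indices per branch).
#' @export
setClass("FusionNetwork",
  representation(config = "NetworkConfig", branches = "list",
                 aggregation = "list", dense0 = "list", head = "list",
                 gmlp = "list", outDense = "list", meta = "list"),
  validity = function(object) {
    if (length(object@branches) != 3L) return("expected 3 backbone branches")
    TRUE
  })

#' TrainConfig: optimisation settings
#'
#' Defaults follow the reference training recipe: Adam, learning rate 1e-4
#' decaying on validation plateau to a floor of 1e-5, batch size 32, 100
#' epochs.
#'
#' @slot lr initial learning rate; lrMin the floor the schedule never crosses.
#' @slot batchSize minibatch size; epochs training epochs.
#' @slot optimizer optimiser name (only "adam" is implemented).
#' @slot seed integer seed controlling all run randomness.
#' @slot schedFactor multiplicative decay on plateau; schedPatience epochs of
#'   non-improving validation loss before decaying.
#' @slot gradClip global gradient-norm clip (0 disables).
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", lrMin = "numeric", batchSize = "integer",
                 epochs = "integer", optimizer = "character", seed = "integer",
                 schedFactor = "numeric", schedPatience = "integer",
                 gradClip = "numeric"),
  validity = function(object) {
    if (!(object@lr >= object@lrMin && object@lrMin > 0))
      return("need lr >= lrMin > 0")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@optimizer != "adam") return("only the adam optimizer is implemented")
    TRUE
  })

#' MetricsReport: classification evaluation summary
#'
#' @slot accuracy overall accuracy in percent.
#' @slot weighted named numeric(3): support-weighted precision, recall, F1
#'   (percent). Weighted recall equals accuracy by construction.
#' @slot macro named numeric(3): unweighted class means (percent).
#' @slot perClass data.frame of per-class precision/recall/F1/support.
#' @slot confusion K x K count matrix (rows = truth, columns = predicted).
#' @slot roc per-class one-vs-rest ROC curves (list of data.frames with
#'   `fpr`, `tpr` and an `auc` attribute), or empty when probabilities were
#'   unavailable.
#' @slot classes class vocabulary evaluated.
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric", weighted = "numeric", macro = "numeric",
                 perClass = "data.frame", confusion = "matrix", roc = "list",
                 classes = "character"),
  validity = function(object) {
    if (nrow(object@confusion) != length(object@classes))
      return("confusion matrix size does not match class count")
    TRUE
  })

#' TrainingResult: a fitted network with its history
#'
#' @slot network the fitted [FusionNetwork-class] (best-validation checkpoint
#'   when a validation set was available, final epoch otherwise).
#' @slot finalNetwork the network after the last epoch.
#' @slot history per-epoch data.frame: train loss, validation loss and
#'   accuracy, learning rate.
#' @slot bestEpoch epoch index of the retained checkpoint.
#' @export
setClass("TrainingResult",
  representation(network = "FusionNetwork", finalNetwork = "FusionNetwork",
                 history = "data.frame", bestEpoch = "integer"))

#' CamMap: a gradient-weighted class-activation map
#'
#' @slot heatmap non-negative matrix on the chosen layer's spatial grid,
#'   max-normalised to 1 when nonzero.
#' @slot targetClass target class index (1-based).
#' @slot layerId branch/layer identifier the map was computed at.
#' @export
setClass("CamMap",
  representation(heatmap = "matrix", targetClass = "integer",
                 layerId = "character"),
  validity = function(object) {
    if (any(object@heatmap < 0)) return("heatmap entries must be >= 0")
    TRUE
  })

## --- accessors --------------------------------------------------------------

#' @describeIn BodyMap Number of registered regions.
#' @param x a BodyMap.
#' @export
setMethod("bodyMapSize", "BodyMap", function(x) nrow(x@entries))

#' @describeIn BodyMap Registered location IDs in ascending order.
#' @export
setMethod("locationIds", "BodyMap",
          function(x) sort(x@entries$location_id))

#' @describeIn BodyMap Anatomical name for a registered ID (error otherwise).
#' @param id integer location ID.
#' @export
setMethod("lookupLocation", "BodyMap", function(x, id) {
  i <- match(id, x@entries$location_id)
  if (anyNA(i))
    stop("location_id ", paste(id[is.na(i)], collapse = ", "),
         " not registered in this body map", call. = FALSE)
  x@entries$name[i]
})

#' @describeIn WoundManifest Record table (ordered).
#' @param x a WoundManifest.
#' @export
setMethod("manifestRecords", "WoundManifest", function(x) x@records)

#' @describeIn WoundManifest Ordered class vocabulary.
#' @export
setMethod("classLabels", "WoundManifest", function(x) x@classes)

#' @export
setMethod("length", "WoundManifest", function(x) nrow(x@records))

#' @describeIn DatasetSplit Training subset.
#' @param x a DatasetSplit.
#' @export
setMethod("trainSet", "DatasetSplit", function(x) x@train)

#' @describeIn DatasetSplit Validation subset.
#' @export
setMethod("valSet", "DatasetSplit", function(x) x@val)

#' @describeIn DatasetSplit Test subset.
#' @export
setMethod("testSet", "DatasetSplit", function(x) x@test)

#' @describeIn DatasetSplit Seed, fractions and achieved per-class counts.
#' @export
setMethod("splitMetadata", "DatasetSplit", function(x) x@metadata)

#' @describeIn FusionNetwork Configuration used to build the network.
#' @param x a FusionNetwork.
#' @export
setMethod("netConfig", "FusionNetwork", function(x) x@config)

#' @describeIn MetricsReport Overall accuracy (percent).
#' @param x a MetricsReport.
#' @export
setMethod("accuracy", "MetricsReport", function(x) x@accuracy)

#' @describeIn MetricsReport Confusion-count matrix (truth x predicted).
#' @export
setMethod("confusionMatrix", "MetricsReport", function(x) x@confusion)

#' @describeIn MetricsReport Per-class precision/recall/F1/support.
#' @export
setMethod("perClassMetrics", "MetricsReport", function(x) x@perClass)

#' @describeIn MetricsReport Support-weighted precision/recall/F1 (percent).
#' @export
setMethod("weightedMetrics", "MetricsReport", function(x) x@weighted)

#' @describeIn MetricsReport Macro-averaged precision/recall/F1 (percent).
#' @export
setMethod("macroMetrics", "MetricsReport", function(x) x@macro)

#' @describeIn MetricsReport Per-class one-vs-rest ROC curves.
#' @export
setMethod("rocCurves", "MetricsReport", function(x) x@roc)

#' @describeIn CamMap The normalised heatmap matrix.
#' @param x a CamMap.
#' @export
setMethod("camHeatmap", "CamMap", function(x) x@heatmap)

#' @describeIn TrainingResult Per-epoch history table.
#' @param x a TrainingResult.
#' @export
setMethod("trainingHistory", "TrainingResult", function(x) x@history)

#' @describeIn TrainingResult The retained (best-validation) network.
#' @export
setMethod("fittedNetwork", "TrainingResult", function(x) x@network)

## --- show methods -----------------------------------------------------------

setMethod("show", "BodyMap", function(object) {
  cat("BodyMap with", nrow(object@entries), "regions",
      sprintf("(IDs %d..%d)\n", min(object@entries$location_id),
              max(object@entries$location_id)))
})

setMethod("show", "WoundManifest", function(object) {
  cat("WoundManifest:", nrow(object@records), "records,",
      length(object@classes), "classes (",
      paste(object@classes, collapse = ", "), ")\n")
  if (nrow(object@records)) {
    tb <- table(factor(object@records$label, levels = object@classes))
    cat("  per class:", paste(names(tb), as.integer(tb), sep = "=",
                              collapse = ", "), "\n")
  }
})

setMethod("show", "DatasetSplit", function(object) {
  cat("DatasetSplit: train", nrow(object@train@records),
      "/ val", nrow(object@val@records),
      "/ test", nrow(object@test@records), "records\n")
})

setMethod("show", "FusionNetwork", function(object) {
  cat(describeNetwork(object), sep = "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d samples, %d classes\n",
              sum(object@confusion), length(object@classes)))
  cat(sprintf("  accuracy %.2f%% | weighted P %.2f%% R %.2f%% F1 %.2f%%\n",
              object@accuracy, object@weighted["precision"],
              object@weighted["recall"], object@weighted["f1"]))
})

setMethod("show", "CamMap", function(object) {
  cat(sprintf("CamMap %dx%d at %s (target class %d), max %.3f\n",
              nrow(object@heatmap), ncol(object@heatmap), object@layerId,
              object@targetClass, max(object@heatmap)))
})
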