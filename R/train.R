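## Loss, optimisation, the training loop, evaluation, cross-validation and
## the class-subset experiment grid.

#' Cross-entropy loss
#'
#' Multi-class cross-entropy `L = -sum_i y_i log(p_i)`; for a hard label
#' this reduces to `-log(p[y])`. Probabilities are clamped at 1e-12 for
#' numerical safety.
#'
#' @param p Probability vector over K classes (non-negative, summing to 1
#'   within 1e-6), or a (K, N) matrix of probability columns.
#' @param y True class: 1-based index, a one-hot vector of length K, or for
#'   matrix `p` a vector of N indices.
#' @return Loss value(s), `>= 0`; the mean over columns for matrix input.
#' @examples
#' crossEntropy(rep(1 / 6, 6), 3)   # log(6)
#' @export
crossEntropy <- function(p, y, eps = 1e-12) {
  if (is.matrix(p)) {
    wfAssert(all(p >= -eps) && all(abs(colSums(p) - 1) < 1e-6),
             "columns of p must be probability vectors")
    return(mean(-log(pmax(p[cbind(as.integer(y), seq_len(ncol(p)))], eps))))
  }
  wfAssert(all(p >= -eps) && abs(sum(p) - 1) < 1e-6,
           "p must be a probability vector (non-negative, sum 1)")
  if (length(y) == length(p) && length(y) > 1) {
    return(-sum(y * log(pmax(p, eps))))
  }
  -log(pmax(p[as.integer(y)], eps))
}

#' Binary cross-entropy
#'
#' `L = -sum_i [ y_i log(p_i) + (1 - y_i) log(1 - p_i) ]`.
#'
#' @param p Predicted probability (scalar or vector) of the positive class.
#' @param y Binary label(s) in \{0, 1\}.
#' @return Summed loss, `>= 0`.
#' @examples
#' binaryCrossEntropy(0.8, 1)  # -log(0.8)
#' @export
binaryCrossEntropy <- function(p, y, eps = 1e-12) {
  wfAssert(all(p >= 0 & p <= 1), "p must lie in [0,1]")
  wfAssert(all(y %in% c(0, 1)), "y must be binary")
  -sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam with learning rate 1e-4,
#' plateau decay to a floor of 1e-5, batch size 32, 100 epochs. Desk-scale
#' runs typically override `lr`, `batchSize` and `epochs`.
#'
#' @param lr Initial learning rate; `lrMin` the floor the schedule never
#'   crosses.
#' @param batchSize Minibatch size. @param epochs Training epochs.
#' @param seed Integer seed controlling all run randomness.
#' @param schedFactor Plateau decay factor; `schedPatience` epochs without
#'   improvement before decaying.
#' @param gradClip Global gradient-norm clip applied before each Adam step
#'   (0 disables). Default 1, which tames loss spikes on sharp landscapes.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(lr = 1e-4, lrMin = 1e-5, batchSize = 32L,
                        epochs = 100L, seed = 1L, schedFactor = 0.5,
                        schedPatience = 5L, gradClip = 1) {
  methods::new("TrainConfig", lr = lr, lrMin = lrMin,
               batchSize = as.integer(batchSize), epochs = as.integer(epochs),
               optimizer = "adam", seed = as.integer(seed),
               schedFactor = schedFactor,
               schedPatience = as.integer(schedPatience),
               gradClip = gradClip)
}

## One Adam step over aligned parameter/gradient/state trees.
adamStep <- function(p, g, m, v, t, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (treeIsLeaf(p)) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    return(list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v))
  }
  for (i in seq_along(p)) {
    r <- adamStep(p[[i]], g[[i]], m[[i]], v[[i]], t, lr, b1, b2, eps)
    p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
  }
  list(p = p, m = m, v = v)
}

## Load all images of a manifest (resized raw, EBImage layout).
loadManifestImages <- function(manifest, imageRoot, size) {
  r <- manifestRecords(manifest)
  lapply(r$image, function(pth) {
    full <- if (grepl("^(/|[A-Za-z]:)", pth)) pth else file.path(imageRoot, pth)
    resizeImage(loadImage(full), size, size)
  })
}

#' Train a fusion network
#'
#' Minimises mean cross-entropy on (optionally augmented) training batches
#' with Adam. The learning rate decays by `schedFactor` after
#' `schedPatience` epochs without improvement of the monitored loss
#' (validation loss when a validation set is present, else training loss)
#' and never falls below `lrMin`. When a validation set is present, the
#' checkpoint with the best validation accuracy is retained. All
#' randomness (shuffling, dropout, augmentation) derives from `tc@seed`.
#'
#' @param net A [FusionNetwork-class] (built, untrained or warm).
#' @param split A [DatasetSplit-class]; the test subset is not touched.
#' @param tc A [TrainConfig-class].
#' @param augment Optional [AugmentConfig-class] applied to training images
#'   each epoch (evaluation data always get resize + normalise only).
#' @param bodyMap A [BodyMap-class], required when the network uses the
#'   location branch.
#' @param imageRoot Directory that manifest image paths are relative to.
#' @param verbose Print per-epoch progress.
#' @return A [TrainingResult-class].
#' @export
trainNetwork <- function(net, split, tc, augment = NULL, bodyMap = NULL,
                         imageRoot = ".", verbose = FALSE) {
  methods::validObject(tc)
  cf <- net@config
  trainMan <- trainSet(split)
  valMan <- valSet(split)
  wfAssert(length(trainMan) > 0, "empty training set")
  wfAssert(length(classLabels(trainMan)) == cf@numClasses,
           "manifest has ", length(classLabels(trainMan)),
           " classes but the network was built for ", cf@numClasses)
  classes <- classLabels(trainMan)
  sz <- cf@imageSize
  evalCfg <- augmentConfig(targetSize = c(sz, sz))
  if (!is.null(augment)) {
    augment@targetSize <- c(sz, sz)
    trainTf <- buildTransform(augment, training = TRUE)
  } else {
    trainTf <- buildTransform(evalCfg, training = FALSE)
  }
  evalTf <- buildTransform(evalCfg, training = FALSE)

  rawTrain <- loadManifestImages(trainMan, imageRoot, sz)
  yTrain <- match(manifestRecords(trainMan)$label, classes)
  locTrain <- if (cf@useLocation) {
    wfAssert(!is.null(bodyMap), "location branch enabled: bodyMap is required")
    alignLocations(trainMan, bodyMap)
  } else NULL
  haveVal <- length(valMan) > 0
  if (haveVal) {
    valBatch <- asBatch(lapply(loadManifestImages(valMan, imageRoot, sz),
                               function(im) applyTransform(evalTf, im)))
    yVal <- match(manifestRecords(valMan)$label, classes)
    locVal <- if (cf@useLocation) alignLocations(valMan, bodyMap) else NULL
  }

  set.seed(tc@seed)
  params <- netParams(net)
  mState <- treeZerosLike(params)
  vState <- treeZerosLike(params)
  lr <- tc@lr
  stepT <- 0L
  bestMonitor <- Inf
  sinceImprove <- 0L
  bestValAcc <- -Inf
  bestValLoss <- Inf
  bestParams <- params
  bestEpoch <- 1L
  n <- length(rawTrain)
  hist <- vector("list", tc@epochs)

  for (epoch in seq_len(tc@epochs)) {
    ## fresh augmented view of the training set this epoch
    xs <- lapply(rawTrain, function(im) applyTransform(trainTf, im))
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq.int(1L, n, by = tc@batchSize)) {
      idx <- ord[start:min(start + tc@batchSize - 1L, n)]
      xb <- asBatch(xs[idx])
      lb <- if (cf@useLocation) locTrain[, idx, drop = FALSE] else NULL
      fw <- netForward(net, xb, lb, training = TRUE)
      net <- fw$net
      ce <- nnSoftmaxCrossEntropy(fw$logits, yTrain[idx])
      if (!is.finite(ce$loss))
        stop("non-finite training loss at epoch ", epoch,
             " (lr = ", lr, "); aborting", call. = FALSE)
      losses <- c(losses, ce$loss)
      bw <- netBackward(net, fw$cache, ce$dlogits)
      g <- bw$grads
      if (tc@gradClip > 0) {
        gn <- sqrt(treeSumSq(g))
        if (gn > tc@gradClip)
          g <- treeMap(function(x) x * tc@gradClip / gn, g)
      }
      stepT <- stepT + 1L
      upd <- adamStep(params, g, mState, vState, stepT, lr)
      params <- upd$p; mState <- upd$m; vState <- upd$v
      net <- netSetParams(net, params)
    }
    trainLoss <- mean(losses)
    valLoss <- NA_real_; valAcc <- NA_real_
    if (haveVal) {
      fwv <- netForward(net, valBatch,
                        if (cf@useLocation) locVal else NULL,
                        training = FALSE)
      cev <- nnSoftmaxCrossEntropy(fwv$logits, yVal)
      valLoss <- cev$loss
      valAcc <- 100 * mean(apply(fwv$logits, 2, which.max) == yVal)
      ## best validation accuracy; ties broken by lower validation loss
      if (valAcc > bestValAcc ||
          (valAcc == bestValAcc && valLoss < bestValLoss)) {
        bestValAcc <- valAcc
        bestValLoss <- valLoss
        bestParams <- params
        bestEpoch <- epoch
      }
    }
    monitor <- if (haveVal) valLoss else trainLoss
    if (monitor < bestMonitor - 1e-9) {
      bestMonitor <- monitor
      sinceImprove <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
      if (sinceImprove >= tc@schedPatience) {
        lr <- max(lr * tc@schedFactor, tc@lrMin)
        sinceImprove <- 0L
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                valLoss = valLoss, valAcc = valAcc, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %5.1f  lr %.2e",
                      epoch, trainLoss, valLoss, valAcc, lr))
  }
  if (!haveVal) {
    bestParams <- params
    bestEpoch <- tc@epochs
  }
  methods::new("TrainingResult",
               network = netSetParams(net, bestParams),
               finalNetwork = net,
               history = do.call(rbind, hist),
               bestEpoch = as.integer(bestEpoch))
}

#' Evaluate a network on a manifest
#'
#' Predictions are the argmax of the softmax logits (no augmentation).
#'
#' @param net A trained [FusionNetwork-class].
#' @param manifest Non-empty [WoundManifest-class].
#' @param bodyMap Required when the network uses the location branch.
#' @param imageRoot Directory image paths are relative to.
#' @param batchSize Evaluation batch size.
#' @return A [MetricsReport-class].
#' @export
evaluateNetwork <- function(net, manifest, bodyMap = NULL, imageRoot = ".",
                            batchSize = 32L) {
  wfAssert(length(manifest) > 0, "empty evaluation manifest")
  cf <- net@config
  classes <- classLabels(manifest)
  sz <- cf@imageSize
  tf <- buildTransform(augmentConfig(targetSize = c(sz, sz)), training = FALSE)
  raws <- loadManifestImages(manifest, imageRoot, sz)
  xs <- lapply(raws, function(im) applyTransform(tf, im))
  locs <- if (cf@useLocation) {
    wfAssert(!is.null(bodyMap), "location branch enabled: bodyMap is required")
    alignLocations(manifest, bodyMap)
  } else NULL
  n <- length(xs)
  probs <- matrix(NA_real_, n, cf@numClasses)
  for (start in seq.int(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    fw <- netForward(net, asBatch(xs[idx]),
                     if (cf@useLocation) locs[, idx, drop = FALSE] else NULL,
                     training = FALSE)
    probs[idx, ] <- t(nnSoftmax(fw$logits))
  }
  pred <- classes[max.col(probs, ties.method = "first")]
  truth <- manifestRecords(manifest)$label
  computeMetrics(truth, pred, classes, probs)
}

#' Aggregate cross-validation fold accuracies
#'
#' Arithmetic mean of the fold accuracies (percent), rounded to 2 decimals.
#'
#' @param foldAccuracies Numeric vector of per-fold accuracies in percent.
#' @return The rounded mean.
#' @examples
#' aggregateFoldAccuracies(c(80.01, 80.01, 82.72, 85.34, 84.81))  # 82.58
#' @export
aggregateFoldAccuracies <- function(foldAccuracies) {
  round(mean(foldAccuracies), 2)
}

#' k-fold cross-validation
#'
#' Trains k independent networks on the stratified folds of
#' [makeCvFolds()] (an 80-20 train/test split per fold when k = 5) and
#' reports the fold accuracies and their rounded mean.
#'
#' @param manifest A [WoundManifest-class].
#' @param k Number of folds.
#' @param config A [NetworkConfig-class] for the per-fold networks.
#' @param tc A [TrainConfig-class]; fold f trains with seed `tc@seed + f`.
#' @param augment,bodyMap,imageRoot As in [trainNetwork()].
#' @return list(foldAccuracies, average, reports).
#' @export
runCrossval <- function(manifest, k = 5L, config, tc, augment = NULL,
                        bodyMap = NULL, imageRoot = ".") {
  folds <- makeCvFolds(manifest, k, seed = tc@seed)
  emptyVal <- methods::new("WoundManifest", records = emptyRecords(),
                           classes = classLabels(manifest))
  accs <- numeric(k)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tcf <- tc; tcf@seed <- tc@seed + f
    net <- buildFusionNetwork(config, seed = tc@seed + f)
    split <- methods::new("DatasetSplit", train = folds[[f]]$train,
                          val = emptyVal, test = folds[[f]]$test,
                          metadata = list(fold = f))
    fit <- tryCatch(
      trainNetwork(net, split, tcf, augment, bodyMap, imageRoot),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    rep <- evaluateNetwork(fittedNetwork(fit), folds[[f]]$test, bodyMap,
                           imageRoot)
    reports[[f]] <- rep
    accs[f] <- round(accuracy(rep), 2)
  }
  list(foldAccuracies = accs, average = aggregateFoldAccuracies(accs),
       reports = reports)
}

#' Class-subset experiment grid
#'
#' For every (class subset, split specification) cell: select the classes,
#' split, train a fresh network and evaluate on the test subset, producing
#' one row of accuracy / weighted precision / recall / F1 (percent, 2
#' decimals). Failures are recorded in the row and the grid continues.
#'
#' @param manifest A [WoundManifest-class].
#' @param subsets List of class-symbol vectors.
#' @param splitSpecs List of [SplitSpec-class] objects.
#' @param config Base [NetworkConfig-class] (numClasses is set per cell).
#' @param tc A [TrainConfig-class].
#' @param augment,bodyMap,imageRoot As in [trainNetwork()].
#' @return data.frame with one row per cell.
#' @export
runExperimentGrid <- function(manifest, subsets, splitSpecs, config, tc,
                              augment = NULL, bodyMap = NULL,
                              imageRoot = ".") {
  rows <- list()
  for (sub in subsets) for (sp in splitSpecs) {
    label <- paste(sub, collapse = ",")
    fr <- paste(sp@fractions, collapse = "/")
    row <- data.frame(classes = label, fractions = fr,
                      accuracy = NA_real_, precision = NA_real_,
                      recall = NA_real_, f1 = NA_real_, error = "")
    res <- tryCatch({
      m <- selectClasses(manifest, sub)
      split <- splitDataset(m, sp)
      cfg <- config
      cfg@numClasses <- length(sub)
      net <- buildFusionNetwork(cfg, seed = tc@seed)
      fit <- trainNetwork(net, split, tc, augment, bodyMap, imageRoot)
      evaluateNetwork(fittedNetwork(fit), testSet(split), bodyMap, imageRoot)
    }, error = function(e) e)
    if (methods::is(res, "MetricsReport")) {
      w <- weightedMetrics(res)
      row$accuracy <- round(accuracy(res), 2)
      row$precision <- round(w["precision"], 2)
      row$recall <- round(w["recall"], 2)
      row$f1 <- round(w["f1"], 2)
    } else {
      row$error <- conditionMessage(res)
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
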