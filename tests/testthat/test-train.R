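test_that("cross-entropy matches closed forms and a brute-force oracle", {
  expect_equal(crossEntropy(c(0, 1, 0), 2), 0)
  expect_equal(crossEntropy(rep(1 / 6, 6), 4), log(6), tolerance = 1e-12)
  expect_equal(binaryCrossEntropy(0.8, 1), -log(0.8), tolerance = 1e-12)
  expect_equal(binaryCrossEntropy(0.3, 0), -log(0.7), tolerance = 1e-12)
  ## brute-force oracle: explicit sum over one-hot labels
  set.seed(1)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    p <- stats::runif(K); p <- p / sum(p)
    y <- sample(K, 1)
    yhot <- numeric(K); yhot[y] <- 1
    oracle <- -sum(vapply(seq_len(K),
                          function(i) yhot[i] * log(p[i]), numeric(1)))
    expect_equal(crossEntropy(p, y), oracle, tolerance = 1e-7)
    expect_equal(crossEntropy(p, yhot), oracle, tolerance = 1e-7)
  }
  expect_error(crossEntropy(c(0.5, 0.2), 1), "probability")
  expect_error(crossEntropy(c(-0.2, 1.2), 1), "probability")
})

test_that("batched softmax cross-entropy agrees with the per-sample oracle", {
  set.seed(2)
  K <- 5; N <- 8
  logits <- matrix(rnorm(K * N, sd = 2), K, N)
  y <- sample(K, N, replace = TRUE)
  r <- woundfusion:::nnSoftmaxCrossEntropy(logits, y)
  oracle <- mean(vapply(seq_len(N), function(n) {
    e <- exp(logits[, n] - max(logits[, n]))
    p <- e / sum(e)
    -log(p[y[n]])
  }, numeric(1)))
  expect_equal(r$loss, oracle, tolerance = 1e-7)
  expect_equal(colSums(r$p), rep(1, N), tolerance = 1e-6)
})

test_that("metrics: identities, confusion algebra, absent classes", {
  ## K = 2 with confusion counts TP=9, FN=1, FP=2, TN=8
  truth <- c(rep("D", 10), rep("V", 10))
  pred <- c(rep("D", 9), "V", rep("D", 2), rep("V", 8))
  r <- computeMetrics(truth, pred, c("D", "V"))
  expect_equal(accuracy(r), 85)
  cm <- confusionMatrix(r)
  expect_equal(as.vector(cm), c(9, 2, 1, 8))
  expect_equal(rowSums(cm), c(D = 10, V = 10))   # row sums = support
  precD <- 9 / 11; precV <- 8 / 9
  recD <- 0.9; recV <- 0.8
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(unname(weightedMetrics(r)["precision"]),
               100 * (precD + precV) / 2, tolerance = 1e-9)
  expect_equal(unname(weightedMetrics(r)["f1"]),
               100 * (f1(precD, recD) + f1(precV, recV)) / 2,
               tolerance = 1e-9)
  ## weighted recall equals accuracy exactly
  expect_equal(unname(weightedMetrics(r)["recall"]), accuracy(r),
               tolerance = 1e-9)
  ## all-correct predictions: A = P = R = F = 100
  rp <- computeMetrics(truth, truth, c("D", "V"))
  expect_equal(accuracy(rp), 100)
  expect_equal(unname(weightedMetrics(rp)), rep(100, 3))
  ## a class absent from the evaluation is flagged NA, averages over present
  ra <- computeMetrics(truth, pred, c("D", "V", "S"))
  expect_true(is.na(perClassMetrics(ra)$recall[3]))
  expect_equal(unname(weightedMetrics(ra)["recall"]), accuracy(ra),
               tolerance = 1e-9)
})

test_that("ROC curves are produced per class with sane AUCs", {
  set.seed(3)
  truth <- rep(c("D", "V"), each = 25)
  probsD <- c(stats::rbeta(25, 4, 2), stats::rbeta(25, 2, 4))
  probs <- cbind(probsD, 1 - probsD)
  pred <- ifelse(probsD > 0.5, "D", "V")
  r <- computeMetrics(truth, pred, c("D", "V"), probs)
  expect_setequal(names(rocCurves(r)), c("D", "V"))
  auc <- attr(rocCurves(r)$D, "auc")
  expect_gt(auc, 0.5)
  expect_true(all(rocCurves(r)$D$fpr >= 0 & rocCurves(r)$D$tpr <= 1))
})

test_that("fold-accuracy aggregation reproduces printed-table arithmetic", {
  expect_equal(aggregateFoldAccuracies(c(80.01, 80.01, 82.72, 85.34, 84.81)),
               82.58)
  expect_equal(aggregateFoldAccuracies(c(81.42, 80.71, 80.71, 81.42, 87.14)),
               82.28)
  expect_equal(aggregateFoldAccuracies(rep(91.3, 5)), 91.3)
})

test_that("training is seed-deterministic and the loss decreases", {
  fx <- separableDataset()
  sub <- selectClasses(fx$manifest, c("BG", "D"))
  split <- trainOnlySplit(sub)
  cfg <- networkConfig(numClasses = 2L, imageSize = 32L, dropout = 0)
  tc <- trainConfig(lr = 1e-3, batchSize = 8L, epochs = 2L, seed = 31L)
  f1 <- trainNetwork(buildFusionNetwork(cfg, seed = 1), split, tc,
                     imageRoot = fx$dir)
  f2 <- trainNetwork(buildFusionNetwork(cfg, seed = 1), split, tc,
                     imageRoot = fx$dir)
  expect_identical(trainingHistory(f1)$trainLoss[1],
                   trainingHistory(f2)$trainLoss[1])
  expect_identical(trainingHistory(f1), trainingHistory(f2))
  ## loss decreases over the first epochs (median over 5 seeds)
  drops <- vapply(1:5, function(s) {
    tcs <- trainConfig(lr = 1e-3, batchSize = 8L, epochs = 4L, seed = s)
    h <- trainingHistory(trainNetwork(buildFusionNetwork(cfg, seed = s),
                                      split, tcs, imageRoot = fx$dir))
    h$trainLoss[4] - h$trainLoss[1]
  }, numeric(1))
  expect_lt(stats::median(drops), 0)
})

test_that("the learning-rate schedule floors exactly at lrMin", {
  fx <- separableDataset()
  sub <- selectClasses(fx$manifest, c("BG", "D"))
  split <- trainOnlySplit(sub)
  cfg <- networkConfig(numClasses = 2L, imageSize = 32L, dropout = 0)
  ## lr so small that the loss plateaus immediately; patience 1 forces a
  ## decay nearly every epoch
  tc <- trainConfig(lr = 1e-9, lrMin = 5e-10, batchSize = 16L, epochs = 8L,
                    seed = 2L, schedFactor = 0.1, schedPatience = 1L)
  h <- trainingHistory(trainNetwork(buildFusionNetwork(cfg, seed = 2), split,
                                    tc, imageRoot = fx$dir))
  expect_equal(min(h$lr), 5e-10)
  expect_equal(h$lr[nrow(h)], 5e-10)          # reaches the floor and stays
  expect_true(all(h$lr >= 5e-10))
})

test_that("training errors are informative", {
  cfg <- networkConfig(numClasses = 2L, imageSize = 32L)
  net <- buildFusionNetwork(cfg, seed = 1)
  empty <- woundfusion:::woundManifest(classes = c("D", "V"))
  split <- methods::new("DatasetSplit", train = empty, val = empty,
                        test = empty, metadata = list())
  expect_error(trainNetwork(net, split, trainConfig()), "empty training set")
})

test_that("cross-validation trains k models and aggregates their accuracy", {
  fx <- separableDataset()
  sub <- selectClasses(fx$manifest, c("BG", "D"))
  cfg <- networkConfig(numClasses = 2L, imageSize = 32L, dropout = 0)
  tc <- trainConfig(lr = 1e-3, batchSize = 8L, epochs = 3L, seed = 7L)
  cv <- runCrossval(sub, k = 2L, cfg, tc, imageRoot = fx$dir)
  expect_length(cv$foldAccuracies, 2L)
  expect_equal(cv$average, aggregateFoldAccuracies(cv$foldAccuracies))
  expect_true(all(cv$foldAccuracies >= 0 & cv$foldAccuracies <= 100))
})

test_that("the experiment grid runs every cell and is reproducible", {
  fx <- separableDataset()
  cfg <- networkConfig(numClasses = 2L, imageSize = 32L, dropout = 0)
  tc <- trainConfig(lr = 1e-3, batchSize = 8L, epochs = 2L, seed = 5L)
  subsets <- list(c("BG", "D"), c("N", "P"))
  specs <- list(splitSpec(c(0.6, 0.15, 0.25), seed = 4L))
  g1 <- runExperimentGrid(fx$manifest, subsets, specs, cfg, tc,
                          imageRoot = fx$dir)
  expect_equal(nrow(g1), 2L)
  expect_true(all(g1$error == ""))
  expect_true(all(is.finite(g1$accuracy)))
  expect_equal(g1$recall, g1$accuracy)       # weighted recall == accuracy
  g2 <- runExperimentGrid(fx$manifest, subsets, specs, cfg, tc,
                          imageRoot = fx$dir)
  expect_identical(g1, g2)
  ## a failing cell is recorded without stopping the grid
  gBad <- runExperimentGrid(fx$manifest, list(c("BG", "D"), c("S", "V")),
                            specs, cfg, tc, imageRoot = fx$dir)
  expect_equal(nrow(gBad), 2L)
  expect_true(nzchar(gBad$error[2]))          # S, V absent from the fixture
  expect_true(is.na(gBad$accuracy[2]))
  expect_equal(gBad$classes[1], "BG,D")
})
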