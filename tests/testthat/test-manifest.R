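test_that("manifest CSV round-trip preserves records and order", {
  m <- recordManifest(7L)
  p <- file.path(tempdir(), "man.csv")
  writeManifest(m, p)
  m2 <- readManifest(p)
  expect_identical(manifestRecords(m2), manifestRecords(m))
  expect_identical(classLabels(m2), classLabels(m))
})

test_that("manifests validate labels and tolerate empty record sections", {
  p <- file.path(tempdir(), "six.csv")
  writeLines(c("image,label,location_id,group_id",
               "a.png,BG,,g1", "b.png,N,,g1", "c.png,D,135,g2",
               "d.png,P,300,g2", "e.png,S,400,g3", "f.png,V,178,g3"), p)
  m <- readManifest(p)
  expect_identical(classLabels(m), c("BG", "N", "D", "P", "S", "V"))
  expect_true(is.na(manifestRecords(m)$location_id[1]))

  pe <- file.path(tempdir(), "empty.csv")
  writeLines("image,label,location_id,group_id", pe)
  expect_equal(length(readManifest(pe)), 0L)

  px <- file.path(tempdir(), "badlab.csv")
  writeLines(c("image,label,location_id,group_id", "a.png,X,,g"), px)
  expect_error(readManifest(px), "allowed: BG, N, D, P, S, V")
})

test_that("class-subset selection filters records and resets the vocabulary", {
  m <- countsManifest(c(BG = 5, N = 4, D = 6, V = 3))
  s <- selectClasses(m, c("N", "D"))
  expect_identical(classLabels(s), c("N", "D"))
  expect_equal(length(s), 10L)
  expect_true(all(manifestRecords(s)$label %in% c("N", "D")))
  ## order preserved, counts add up per class (brute force)
  tb <- table(manifestRecords(s)$label)
  expect_equal(as.integer(tb[c("N", "D")]), c(4L, 6L))
  ## full vocabulary subset is the identity on records
  full <- selectClasses(m, classLabels(m))
  expect_identical(manifestRecords(full), manifestRecords(m))
  expect_error(selectClasses(m, c("N", "Q")), "not in manifest")
  expect_error(selectClasses(m, "N"), "at least 2")
})

test_that("floor split rule gives the documented per-class counts", {
  ## venous ROI, 60/15/25: 247 -> 148/37/62; surgical 70/15/15: 164 -> 114/24/26
  m <- countsManifest(c(V = 247))
  sp <- splitDataset(m, splitSpec(c(0.60, 0.15, 0.25), seed = 3))
  expect_equal(vapply(list(trainSet(sp), valSet(sp), testSet(sp)), length,
                      integer(1)), c(148L, 37L, 62L))
  m2 <- countsManifest(c(S = 164))
  sp2 <- splitDataset(m2, splitSpec(c(0.70, 0.15, 0.15), seed = 3))
  expect_equal(vapply(list(trainSet(sp2), valSet(sp2), testSet(sp2)), length,
                      integer(1)), c(114L, 24L, 26L))
  ## n = 1: floors are 0, the remainder goes to test
  m3 <- countsManifest(c(D = 1))
  expect_warning(sp3 <- splitDataset(m3, splitSpec(c(0.7, 0.15, 0.15))),
                 "consider merging")
  expect_equal(length(testSet(sp3)), 1L)
  expect_equal(length(trainSet(sp3)), 0L)
})

test_that("splits partition the records and are seed-reproducible", {
  m <- countsManifest(c(BG = 23, D = 31, V = 17))
  sp <- splitDataset(m, splitSpec(c(0.6, 0.15, 0.25), seed = 9))
  imgs <- lapply(list(trainSet(sp), valSet(sp), testSet(sp)),
                 function(x) manifestRecords(x)$image)
  expect_equal(sum(lengths(imgs)), length(m))
  expect_equal(length(unique(unlist(imgs))), length(m))   # pairwise disjoint
  expect_setequal(unlist(imgs), manifestRecords(m)$image)
  ## per-class partition
  for (cl in classLabels(m)) {
    n <- sum(manifestRecords(m)$label == cl)
    parts <- vapply(list(trainSet(sp), valSet(sp), testSet(sp)),
                    function(x) sum(manifestRecords(x)$label == cl),
                    numeric(1))
    expect_equal(sum(parts), n)
  }
  sp2 <- splitDataset(m, splitSpec(c(0.6, 0.15, 0.25), seed = 9))
  expect_identical(manifestRecords(trainSet(sp2)),
                   manifestRecords(trainSet(sp)))
  sp3 <- splitDataset(m, splitSpec(c(0.6, 0.15, 0.25), seed = 10))
  expect_false(identical(manifestRecords(trainSet(sp3)),
                         manifestRecords(trainSet(sp))))
})

test_that("group-aware splitting never splits a wound group", {
  m <- recordManifest(30L)
  sp <- splitDataset(m, splitSpec(c(0.6, 0.2, 0.2), seed = 2,
                                  groupAware = TRUE))
  gs <- lapply(list(trainSet(sp), valSet(sp), testSet(sp)),
               function(x) unique(manifestRecords(x)$group_id))
  expect_length(intersect(gs[[1]], gs[[2]]), 0L)
  expect_length(intersect(gs[[1]], gs[[3]]), 0L)
  expect_length(intersect(gs[[2]], gs[[3]]), 0L)
  expect_equal(sum(vapply(list(trainSet(sp), valSet(sp), testSet(sp)),
                          length, integer(1))), length(m))
  expect_true(is.list(splitMetadata(sp)$achievedCounts))
})

test_that("cross-validation folds are stratified, disjoint and exhaustive", {
  m <- countsManifest(c(D = 50, V = 50))
  folds <- makeCvFolds(m, k = 5L, seed = 4)
  testSets <- lapply(folds, function(f) manifestRecords(f$test)$image)
  expect_equal(lengths(testSets), rep(20L, 5L))          # 80-20 per fold
  expect_equal(length(unique(unlist(testSets))), 100L)   # disjoint union
  expect_setequal(unlist(testSets), manifestRecords(m)$image)
  for (f in folds) {
    expect_equal(length(f$train) + length(f$test), 100L)
    expect_equal(sum(manifestRecords(f$test)$label == "D"), 10L)
  }
  ## k = 2 on 4 records of one class: test sizes (2, 2)
  m2 <- countsManifest(c(D = 4, V = 4))
  f2 <- makeCvFolds(m2, k = 2L, seed = 1)
  expect_equal(vapply(f2, function(f) length(f$test), integer(1)), c(4L, 4L))
  expect_error(makeCvFolds(countsManifest(c(D = 3, V = 9)), k = 5L),
               "fewer than k")
})

test_that("writeSplit emits three manifests plus a JSON sidecar", {
  m <- countsManifest(c(D = 9, V = 12))
  sp <- splitDataset(m, splitSpec(c(0.6, 0.2, 0.2), seed = 1))
  dir <- file.path(tempdir(), "splitout")
  writeSplit(sp, dir)
  expect_true(all(file.exists(file.path(dir, c("train.csv", "val.csv",
                                               "test.csv", "split.json")))))
  meta <- jsonlite::read_json(file.path(dir, "split.json"))
  expect_equal(meta$seed, 1L)
})
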