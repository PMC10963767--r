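test_that("generation bookkeeping: counts, classes, files", {
  fx <- separableDataset()
  m <- fx$manifest
  expect_equal(length(m), 32L)
  expect_identical(classLabels(m), c("BG", "N", "D", "P"))
  r <- manifestRecords(m)
  expect_equal(as.vector(table(r$label)[classLabels(m)]), rep(8L, 4L))
  expect_true(all(file.exists(file.path(fx$dir, r$image))))
  expect_true(file.exists(file.path(fx$dir, "manifest.csv")))
  ## BG and N have no location; wound classes do
  expect_true(all(is.na(r$location_id[r$label %in% c("BG", "N")])))
  expect_true(all(!is.na(r$location_id[r$label %in% c("D", "P")])))
  ## groups cycle within each class
  expect_equal(length(unique(r$group_id[r$label == "D"])), 4L)
})

test_that("same spec and seed reproduce byte-identical output", {
  spec <- syntheticSpec(classes = c("D", "V"), perClassN = 3L,
                        imageSize = 24L, seed = 77L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  m1 <- generateSynthetic(spec, d1)
  m2 <- generateSynthetic(spec, d2)
  expect_identical(manifestRecords(m1), manifestRecords(m2))
  f1 <- list.files(file.path(d1, "images"), full.names = TRUE)
  f2 <- list.files(file.path(d2, "images"), full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("preferred location sets are disjoint, small and documented", {
  sets <- lapply(c("D", "P", "S", "V"), preferredLocations)
  expect_true(135L %in% preferredLocations("D"))
  all <- unlist(sets)
  expect_equal(length(all), length(unique(all)))      # pairwise disjoint
  expect_lt(length(all), 484L)                        # room for uniform draws
  expect_true(all(all >= 1L & all <= 484L))
  expect_error(preferredLocations("BG"), "no location")
  expect_error(preferredLocations("N"), "no location")
})

test_that("location association: degenerate draw at assoc = 1", {
  spec <- syntheticSpec(classes = c("D", "V"), perClassN = 60L,
                        locationAssoc = 1, seed = 5L)
  m <- generateSynthetic(spec, manifestOnly = TRUE)
  r <- manifestRecords(m)
  expect_true(all(r$location_id[r$label == "D"] %in% preferredLocations("D")))
  expect_true(all(r$location_id[r$label == "V"] %in% preferredLocations("V")))
})

test_that("location association: assoc = 0 draws uniformly over 1..484", {
  spec <- syntheticSpec(classes = c("D", "V"), perClassN = 2500L,
                        locationAssoc = 0, seed = 6L)
  m <- generateSynthetic(spec, manifestOnly = TRUE)
  ids <- manifestRecords(m)$location_id
  expect_equal(length(ids), 5000L)
  tab <- tabulate(ids, nbins = 484L)
  pval <- stats::chisq.test(tab, p = rep(1 / 484, 484))$p.value
  expect_gt(pval, 0.01)
})

test_that("class appearances are separable; ambiguous pairs share one", {
  ## mean colour separates classes by construction: lesion hues differ
  woundfusion:::withSeed(1, {
    imD <- woundfusion:::synthImage("D", 48)
    imP <- woundfusion:::synthImage("P", 48)
    imBG <- woundfusion:::synthImage("BG", 48)
  })
  chMean <- function(im) apply(im, 3, mean)
  expect_gt(sum(abs(chMean(imD) - chMean(imP))), 0.1)
  expect_gt(sum(abs(chMean(imD) - chMean(imBG))), 0.2)
  ## an ambiguous pair renders both classes with the first class's look
  spec <- syntheticSpec(classes = c("D", "V"), perClassN = 4L,
                        imageSize = 24L, ambiguousPair = c("D", "V"),
                        seed = 9L)
  d <- file.path(tempdir(), "ambig")
  m <- generateSynthetic(spec, d)
  imgs <- lapply(manifestRecords(m)$image,
                 function(p) loadImage(file.path(d, p)))
  mD <- sapply(imgs[1:4], function(im) apply(im, 3, mean))
  mV <- sapply(imgs[5:8], function(im) apply(im, 3, mean))
  ## per-channel means of the two classes are statistically indistinguishable
  expect_lt(sum(abs(rowMeans(mD) - rowMeans(mV))), 0.15)
})

test_that("unwritable output directory raises an I/O error", {
  spec <- syntheticSpec(classes = c("D", "V"), perClassN = 1L, seed = 1L)
  expect_error(generateSynthetic(spec, "/proc/definitely/not/writable"))
})
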