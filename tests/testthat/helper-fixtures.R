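## Shared fixtures: synthetic datasets are generated once per test run and
## cached in the session temp directory.

.fixtureEnv <- new.env(parent = emptyenv())

## Separable 4-class dataset, 8 images per class, 32 px.
separableDataset <- function() {
  if (is.null(.fixtureEnv$sep)) {
    dir <- file.path(tempdir(), "wf-sep")
    spec <- syntheticSpec(classes = c("BG", "N", "D", "P"), perClassN = 8L,
                          imageSize = 32L, seed = 11L)
    .fixtureEnv$sep <- list(dir = dir, manifest = generateSynthetic(spec, dir))
  }
  .fixtureEnv$sep
}

## A small manifest without images (pure record-level tests).
recordManifest <- function(n = 12L, classes = c("D", "V")) {
  woundManifest(data.frame(
    image = sprintf("img_%02d.png", seq_len(n)),
    label = rep(classes, length.out = n),
    location_id = rep(c(135L, 178L), length.out = n),
    group_id = sprintf("g%02d", rep(seq_len(max(1L, n %/% 3L)),
                                    length.out = n))),
    classes = classes)
}

## Balanced manifest with per-class counts, fabricated records.
countsManifest <- function(counts) {
  rows <- do.call(rbind, lapply(names(counts), function(cl) {
    data.frame(image = sprintf("%s_%04d.png", cl, seq_len(counts[[cl]])),
               label = cl, location_id = NA_integer_,
               group_id = sprintf("%s_g%d", cl,
                                  seq_len(counts[[cl]]) %% 7L))
  }))
  woundManifest(rows, classes = names(counts))
}

emptySibling <- function(manifest) {
  woundfusion:::woundManifest(classes = classLabels(manifest))
}

trainOnlySplit <- function(manifest) {
  methods::new("DatasetSplit", train = manifest,
               val = emptySibling(manifest), test = emptySibling(manifest),
               metadata = list())
}

randomImage <- function(size = 32L, seed = NULL) {
  f <- function() array(stats::runif(size * size * 3), c(size, size, 3L))
  if (is.null(seed)) f() else woundfusion:::withSeed(seed, f())
}
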