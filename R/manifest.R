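## Dataset model: manifest construction and I/O, class-subset selection,
## the deterministic per-class floor split rule, and stratified
## cross-validation folds.

emptyRecords <- function() {
  data.frame(image = character(0), label = character(0),
             location_id = integer(0), group_id = character(0))
}

#' Construct a wound manifest
#'
#' @param records data.frame with columns `image`, `label`, `location_id`
#'   (integer, NA allowed), `group_id`. Missing columns are added empty.
#' @param classes Ordered class vocabulary. Default: the canonical symbols
#'   (BG, N, D, P, S, V) restricted to the labels present, in canonical
#'   order.
#' @return A [WoundManifest-class].
#' @export
woundManifest <- function(records = emptyRecords(), classes = NULL) {
  if (is.null(records$location_id)) records$location_id <- NA_integer_
  if (is.null(records$group_id)) records$group_id <- ""
  records$image <- as.character(records$image)
  records$label <- as.character(records$label)
  records$location_id <- suppressWarnings(as.integer(records$location_id))
  records$group_id <- as.character(records$group_id)
  records <- records[, c("image", "label", "location_id", "group_id")]
  rownames(records) <- NULL
  if (is.null(classes)) {
    present <- unique(records$label)
    bad <- setdiff(present, CLASS_SYMBOLS)
    if (length(bad))
      stop("unknown label symbol(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(CLASS_SYMBOLS, collapse = ", "), ")",
           call. = FALSE)
    classes <- CLASS_SYMBOLS[CLASS_SYMBOLS %in% present]
    if (!length(classes)) classes <- CLASS_SYMBOLS
  }
  methods::new("WoundManifest", records = records, classes = classes)
}

#' Read a manifest CSV
#'
#' Expects the header `image,label,location_id,group_id`; `location_id` may
#' be blank (background / normal-skin records). Unknown label symbols are
#' rejected with the list of allowed symbols.
#'
#' @param path CSV file path.
#' @param classes Optional explicit class vocabulary.
#' @return A [WoundManifest-class]; record order is the file's row order.
#' @export
readManifest <- function(path, classes = NULL) {
  wfAssert(file.exists(path), "manifest not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("image", "label", "location_id", "group_id")
  if (!all(need %in% names(raw)))
    stop("manifest must have header ", paste(need, collapse = ","),
         call. = FALSE)
  raw$location_id[!nzchar(raw$location_id)] <- NA_character_
  if (!is.null(classes)) {
    bad <- setdiff(unique(raw$label), classes)
    if (length(bad))
      stop("unknown label symbol(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(classes, collapse = ", "), ")", call. = FALSE)
  }
  woundManifest(raw, classes)
}

#' Write a manifest CSV
#'
#' Inverse of [readManifest()]: `readManifest(writeManifest(m, p))` restores
#' records and their order exactly.
#'
#' @param manifest A [WoundManifest-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  r <- manifestRecords(manifest)
  r$location_id <- ifelse(is.na(r$location_id), "", as.character(r$location_id))
  utils::write.csv(r, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a manifest to a class subset
#'
#' Keeps only records whose label belongs to `subset` (order preserved) and
#' resets the class vocabulary to `subset`.
#'
#' @param manifest A [WoundManifest-class].
#' @param subset Character vector of at least two classes, all present in
#'   the manifest's vocabulary.
#' @return A [WoundManifest-class].
#' @export
selectClasses <- function(manifest, subset) {
  wfAssert(length(subset) >= 2L, "class subset must have at least 2 classes")
  bad <- setdiff(subset, classLabels(manifest))
  if (length(bad))
    stop("classes not in manifest vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  r <- manifestRecords(manifest)
  methods::new("WoundManifest", records = r[r$label %in% subset, , drop = FALSE],
               classes = subset)
}

#' Split specification
#'
#' @param fractions numeric(3): train, validation, test fractions (sum 1).
#' @param seed Integer seed for the deterministic per-class shuffle.
#' @param groupAware Keep all records of a wound group in a single subset
#'   (greedy packing; achieved counts may deviate from the floor targets and
#'   are reported in the split metadata).
#' @return A [SplitSpec-class].
#' @export
splitSpec <- function(fractions = c(0.70, 0.15, 0.15), seed = 1L,
                      groupAware = FALSE) {
  methods::new("SplitSpec", fractions = as.numeric(fractions),
               seed = as.integer(seed), groupAware = isTRUE(groupAware))
}

## Per-class subset sizes under the floor rule:
## train = floor(f1 n), val = floor(f2 n), test = remainder.
splitCounts <- function(n, fractions) {
  nTrain <- wfFloor(fractions[1] * n)
  nVal <- wfFloor(fractions[2] * n)
  c(train = nTrain, val = nVal, test = n - nTrain - nVal)
}

#' Deterministic per-class dataset split
#'
#' For each class with n records the training subset receives
#' `floor(train_frac * n)` records, validation `floor(val_frac * n)`, and
#' the test subset the remainder. Assignment within a class follows a
#' seed-deterministic shuffle. With `groupAware = TRUE`, whole wound groups
#' are packed greedily into the subset with the largest remaining deficit,
#' so no group ever spans two subsets; achieved counts are reported in the
#' metadata.
#'
#' @param manifest A [WoundManifest-class].
#' @param spec A [SplitSpec-class].
#' @return A [DatasetSplit-class].
#' @export
splitDataset <- function(manifest, spec) {
  methods::validObject(spec)
  r <- manifestRecords(manifest)
  classes <- classLabels(manifest)
  nNonzero <- sum(spec@fractions > 0)
  assign <- character(nrow(r))
  counts <- list()
  withSeed(spec@seed, {
    for (cl in classes) {
      idx <- which(r$label == cl)
      n <- length(idx)
      if (n == 0L) next
      tgt <- splitCounts(n, spec@fractions)
      counts[[cl]] <- tgt
      if (n < nNonzero)
        warning("class ", cl, " has only ", n, " record(s) for ", nNonzero,
                " nonzero subsets; consider merging or dropping it",
                call. = FALSE)
      if (!spec@groupAware) {
        idx <- idx[sample.int(n)]
        assign[idx[seq_len(tgt["train"])]] <- "train"
        if (tgt["val"] > 0)
          assign[idx[tgt["train"] + seq_len(tgt["val"])]] <- "val"
        rest <- idx[setdiff(seq_len(n), seq_len(tgt["train"] + tgt["val"]))]
        assign[rest] <- "test"
      } else {
        if (any(!nzchar(r$group_id[idx])))
          stop("groupAware split requires a group_id on every record",
               call. = FALSE)
        groups <- split(idx, r$group_id[idx])
        groups <- groups[sample.int(length(groups))]
        deficit <- as.numeric(tgt)
        names(deficit) <- names(tgt)
        for (g in groups) {
          k <- names(deficit)[which.max(deficit)]
          assign[g] <- k
          deficit[k] <- deficit[k] - length(g)
        }
      }
    }
  })
  mk <- function(which) {
    methods::new("WoundManifest", records = r[assign == which, , drop = FALSE],
                 classes = classes)
  }
  achieved <- lapply(stats::setNames(nm = classes), function(cl) {
    vapply(c("train", "val", "test"),
           function(s) sum(assign == s & r$label == cl), numeric(1))
  })
  methods::new("DatasetSplit", train = mk("train"), val = mk("val"),
               test = mk("test"),
               metadata = list(seed = spec@seed, fractions = spec@fractions,
                               groupAware = spec@groupAware,
                               targetCounts = counts,
                               achievedCounts = achieved))
}

#' Write a dataset split to disk
#'
#' Emits `train.csv`, `val.csv`, `test.csv` plus a `split.json` sidecar with
#' the seed, fractions and per-class counts.
#'
#' @param split A [DatasetSplit-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSplit <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeManifest(trainSet(split), file.path(dir, "train.csv"))
  writeManifest(valSet(split), file.path(dir, "val.csv"))
  writeManifest(testSet(split), file.path(dir, "test.csv"))
  jsonlite::write_json(splitMetadata(split),
                       file.path(dir, "split.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Stratified cross-validation folds
#'
#' Partitions the manifest into k folds stratified by class: each class's
#' records are shuffled deterministically and dealt into k nearly equal
#' parts, so the k test sets are pairwise disjoint and union to the full
#' manifest. With k = 5 each (train, test) pair is an 80-20 split.
#'
#' @param manifest A [WoundManifest-class].
#' @param k Number of folds (>= 2); every class must have at least k records.
#' @param seed Integer seed.
#' @return List of k `list(train =, test =)` manifest pairs.
#' @export
makeCvFolds <- function(manifest, k = 5L, seed = 1L) {
  k <- as.integer(k)
  wfAssert(k >= 2L, "k must be >= 2")
  r <- manifestRecords(manifest)
  classes <- classLabels(manifest)
  fold <- integer(nrow(r))
  withSeed(seed, {
    for (cl in classes) {
      idx <- which(r$label == cl)
      n <- length(idx)
      if (n == 0L) next
      if (n < k)
        stop("class ", cl, " has ", n, " records, fewer than k = ", k,
             call. = FALSE)
      idx <- idx[sample.int(n)]
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      fold[idx] <- rep(seq_len(k), times = sizes)
    }
  })
  lapply(seq_len(k), function(i) {
    list(train = methods::new("WoundManifest",
                              records = r[fold != i, , drop = FALSE],
                              classes = classes),
         test = methods::new("WoundManifest",
                             records = r[fold == i, , drop = FALSE],
                             classes = classes))
  })
}
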