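## Desk-scale synthetic wound datasets.
##
## Images are parametric (shapes + noise, no learned generator): each class
## gets a distinct base appearance separable by colour and texture —
## background is a smooth dark gradient, normal skin a noisy skin tone, and
## each wound class an elliptical lesion on skin with class-specific colour,
## granularity and edge darkness. Wound locations are drawn from fixed
## class-preferred body-map region sets with probability `locationAssoc`,
## otherwise uniformly over 1..484, giving a controllable class-location
## association. An optional "ambiguous pair" makes two classes share one
## appearance so that the location becomes the only separating signal — the
## desk-scale analogue of the image+location gain.

## Fixed, pairwise-disjoint preferred region sets (clinical priors: diabetic
## ulcers on the foot, venous on the lower leg / malleolus, pressure over
## bony prominences, surgical on incision sites). Deliberately small — a
## handful of typical sites per aetiology — so that preferred locations
## recur between training and test samples; a one-hot encoding cannot
## generalise to region IDs never seen in training.
.PREF_LOCATIONS <- list(
  D = 130:137,   # foot regions (includes 135, a toe tip)
  V = 175:182,   # lower leg / ankle (includes 178, a medial malleolus)
  P = 300:307,
  S = 400:407)

#' Class-preferred body-map regions
#'
#' Fixed, pairwise-disjoint location ID sets used by the synthetic
#' generator; their union leaves most of the 484 IDs free for uniform
#' draws.
#'
#' @param class A wound class symbol: D, P, S or V.
#' @return Integer vector of location IDs.
#' @export
preferredLocations <- function(class) {
  wfAssert(length(class) == 1L && class %in% names(.PREF_LOCATIONS),
           "class ", class, " has no location (wound classes: D, P, S, V)")
  .PREF_LOCATIONS[[class]]
}

#' Synthetic dataset specification
#'
#' @param classes Ordered subset of BG, N, D, P, S, V (at least 2).
#' @param perClassN Images per class.
#' @param imageSize Square image side in pixels.
#' @param locationAssoc Probability a wound sample's location comes from its
#'   class-preferred set (vs. uniform over 1..484).
#' @param groupsPerClass Wound groups per class (consecutive samples share a
#'   group).
#' @param ambiguousPair Optional two classes that share one appearance.
#' @param seed Integer seed; same spec + seed gives byte-identical output.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(classes = CLASS_SYMBOLS, perClassN = 10L,
                          imageSize = 64L, locationAssoc = 0.9,
                          groupsPerClass = 4L, ambiguousPair = character(0),
                          seed = 1L) {
  methods::new("SyntheticSpec", classes = as.character(classes),
               perClassN = as.integer(perClassN),
               imageSize = as.integer(imageSize),
               locationAssoc = as.numeric(locationAssoc),
               groupsPerClass = as.integer(groupsPerClass),
               ambiguousPair = as.character(ambiguousPair),
               seed = as.integer(seed))
}

## Appearance parameters per class: base colour, lesion colour, lesion
## geometry (eccentricity), texture granularity and edge darkness.
classAppearance <- function(cl) {
  switch(cl,
    BG = list(kind = "gradient"),
    N = list(kind = "skin", noise = 0.035),
    D = list(kind = "lesion", col = c(0.78, 0.55, 0.18), rad = 0.26,
             ecc = 1.4, grain = 0.13, edge = 0.55),
    P = list(kind = "lesion", col = c(0.42, 0.08, 0.16), rad = 0.30,
             ecc = 1.1, grain = 0.02, edge = 0.35),
    S = list(kind = "lesion", col = c(0.85, 0.15, 0.15), rad = 0.33,
             ecc = 4.5, grain = 0.03, edge = 0.75),
    V = list(kind = "lesion", col = c(0.55, 0.28, 0.16), rad = 0.36,
             ecc = 1.2, grain = 0.07, edge = 0.95))
}

## Draw one image for class `cl` (array (size, size, 3) in [0,1]).
## `centerBias` in [-1, 1] shifts the lesion horizontally (used by tests).
synthImage <- function(cl, size, appearanceClass = cl, centerBias = 0) {
  ap <- classAppearance(appearanceClass)
  gx <- matrix(seq_len(size), size, size)       # x (width) index
  gy <- t(gx)                                   # y (height) index
  skin <- function() {
    base <- c(0.80, 0.60, 0.50) + stats::runif(3, -0.06, 0.06)
    img <- array(rep(base, each = size * size), c(size, size, 3))
    img + array(stats::rnorm(size * size * 3, 0, 0.02), dim(img))
  }
  img <- switch(ap$kind,
    gradient = {
      c1 <- stats::runif(3, 0.05, 0.35); c2 <- stats::runif(3, 0.25, 0.6)
      th <- stats::runif(1, 0, pi)
      ramp <- (cos(th) * gx + sin(th) * gy - min(gx)) /
        (sqrt(2) * size)
      ramp <- (ramp - min(ramp)) / (max(ramp) - min(ramp))
      out <- array(0, c(size, size, 3))
      for (ch in 1:3) out[, , ch] <- c1[ch] + (c2[ch] - c1[ch]) * ramp
      out + array(stats::rnorm(size * size * 3, 0, 0.01), dim(out))
    },
    skin = {
      s <- skin()
      s + array(stats::rnorm(size * size * 3, 0, ap$noise), dim(s))
    },
    lesion = {
      s <- skin()
      cx <- size * (0.5 + centerBias * 0.22 + stats::runif(1, -0.08, 0.08))
      cy <- size * (0.5 + stats::runif(1, -0.08, 0.08))
      a <- ap$rad * size * stats::runif(1, 0.85, 1.15)
      b <- a / ap$ecc
      th <- stats::runif(1, 0, pi)
      xr <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
      yr <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
      d <- sqrt((xr / a)^2 + (yr / b)^2)
      inside <- 1 / (1 + exp((d - 1) * 12))        # soft lesion mask
      ring <- exp(-((d - 1)^2) * 18)               # darkened rim
      grain <- matrix(stats::rnorm(size * size, 0, ap$grain), size, size)
      for (ch in 1:3) {
        lesion <- ap$col[ch] * (1 + grain)
        s[, , ch] <- s[, , ch] * (1 - inside) + lesion * inside
        s[, , ch] <- s[, , ch] * (1 - ap$edge * 0.5 * ring)
      }
      s
    })
  pmin(pmax(img, 0), 1)
}

sampleLocation <- function(cl, assoc) {
  if (!cl %in% names(.PREF_LOCATIONS)) return(NA_integer_)
  if (stats::runif(1) < assoc) {
    pref <- .PREF_LOCATIONS[[cl]]
    pref[sample.int(length(pref), 1L)]
  } else {
    sample.int(484L, 1L)
  }
}

#' Generate a synthetic dataset
#'
#' Emits `perClassN` PNG images per class under `outDir/images/` plus a
#' manifest CSV, and returns the manifest. Appearance is separable by
#' construction unless two classes are declared ambiguous; wound locations
#' follow the configured class-location association. Same `spec` + seed
#' reproduces byte-identical output.
#'
#' @param spec A [SyntheticSpec-class].
#' @param outDir Output directory (created if needed); with
#'   `manifestOnly = TRUE` no files are written (locations and grouping only,
#'   for statistical checks).
#' @param manifestOnly Skip image synthesis/writing.
#' @return A [WoundManifest-class] whose image paths are relative to
#'   `outDir`.
#' @export
generateSynthetic <- function(spec, outDir = NULL, manifestOnly = FALSE) {
  methods::validObject(spec)
  if (!manifestOnly) {
    wfAssert(!is.null(outDir), "outDir is required unless manifestOnly = TRUE")
    dir.create(file.path(outDir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    if (!dir.exists(file.path(outDir, "images")))
      stop("cannot create output directory ", outDir, call. = FALSE)
  }
  rows <- vector("list", length(spec@classes) * spec@perClassN)
  k <- 0L
  withSeed(spec@seed, {
    for (cl in spec@classes) {
      appearance <- cl
      if (length(spec@ambiguousPair) == 2L && cl %in% spec@ambiguousPair)
        appearance <- spec@ambiguousPair[1]
      for (i in seq_len(spec@perClassN)) {
        k <- k + 1L
        rel <- file.path("images", sprintf("%s_%03d.png", cl, i))
        if (!manifestOnly) {
          img <- synthImage(cl, spec@imageSize, appearance)
          saveImage(img, file.path(outDir, rel))
        }
        g <- ((i - 1L) %% spec@groupsPerClass) + 1L
        rows[[k]] <- data.frame(
          image = rel, label = cl,
          location_id = sampleLocation(cl, spec@locationAssoc),
          group_id = sprintf("%s_g%02d", cl, g))
      }
    }
  })
  m <- woundManifest(do.call(rbind, rows), classes = spec@classes)
  if (!manifestOnly) writeManifest(m, file.path(outDir, "manifest.csv"))
  m
}
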