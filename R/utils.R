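#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

wfAssert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

## floor() guarded against binary floating point (0.7*100 == 69.9999...).
wfFloor <- function(x, eps = 1e-9) floor(x + eps)

## --- nested parameter trees ------------------------------------------------
## Network parameters live in nested named lists whose leaves are numeric
## arrays. These helpers walk two-or-more trees of identical shape in lockstep
## (used by the Adam optimizer and by parameter counting / copying).

treeIsLeaf <- function(x) is.numeric(x)

treeMap <- function(f, tree) {
  if (treeIsLeaf(tree)) return(f(tree))
  lapply(tree, function(el) treeMap(f, el))
}

treeMap2 <- function(f, a, b) {
  if (treeIsLeaf(a)) return(f(a, b))
  stopifnot(length(a) == length(b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- treeMap2(f, a[[i]], b[[i]])
  out
}

treeMap3 <- function(f, a, b, c) {
  if (treeIsLeaf(a)) return(f(a, b, c))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- treeMap3(f, a[[i]], b[[i]], c[[i]])
  out
}

treeCount <- function(tree) {
  if (treeIsLeaf(tree)) return(length(tree))
  if (length(tree) == 0L) return(0L)
  sum(vapply(tree, treeCount, numeric(1)))
}

treeSumSq <- function(tree) {
  if (treeIsLeaf(tree)) return(sum(tree^2))
  if (length(tree) == 0L) return(0)
  sum(vapply(tree, treeSumSq, numeric(1)))
}

treeZerosLike <- function(tree) treeMap(function(x) {
  z <- x
  z[] <- 0
  z
}, tree)

## Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## He-uniform initialisation for convolution / dense weights.
heInit <- function(dims, fanIn) {
  bound <- sqrt(6 / fanIn)
  array(stats::runif(prod(dims), -bound, bound), dim = dims)
}

## Canonical six-class vocabulary, in the order used throughout.
CLASS_SYMBOLS <- c("BG", "N", "D", "P", "S", "V")
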