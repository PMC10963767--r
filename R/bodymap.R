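## The 484-region anatomical body-map vocabulary and its one-hot encoding.
##
## The method uses location IDs purely numerically: an ID's one-hot position
## is its rank in ascending ID order, so sparse or custom vocabularies work
## unchanged. Only a handful of region names are public knowledge (the
## lower-leg examples); the canonical shipped table carries those and
## systematic placeholder names elsewhere, and can be replaced by any
## user-supplied table.

## Known ID -> name pairs (lower-leg examples of the published body map).
.KNOWN_REGIONS <- c(
  "135" = "Right fifth toe tip",
  "150" = "Right lateral heel",
  "158" = "Right medial malleolus",
  "159" = "Right proximal lateral dorsal foot",
  "178" = "Left medial malleolus",
  "180" = "Left anterior ankle",
  "202" = "Left fifth toe tip",
  "215" = "Left proximal medial plantar foot")

newBodyMap <- function(entries) {
  entries$location_id <- as.integer(entries$location_id)
  entries$name <- as.character(entries$name)
  rownames(entries) <- NULL
  methods::new("BodyMap", entries = entries)
}

#' Canonical 484-region body map
#'
#' Builds the canonical body-map vocabulary with IDs 1..484. The published
#' lower-leg example regions carry their anatomical names; all other IDs get
#' systematic placeholder names (`"Body region 001"`, ...), since the full
#' name table is not public. All package logic depends only on the IDs and
#' the vocabulary size.
#'
#' @return A [BodyMap-class] of size 484.
#' @examples
#' bm <- canonicalBodyMap()
#' bodyMapSize(bm)
#' lookupLocation(bm, 135)
#' @export
canonicalBodyMap <- function() {
  ids <- 1:484
  nm <- sprintf("Body region %03d", ids)
  known <- as.integer(names(.KNOWN_REGIONS))
  nm[known] <- unname(.KNOWN_REGIONS)
  newBodyMap(data.frame(location_id = ids, name = nm))
}

#' Load a body-map vocabulary table
#'
#' Reads a vocabulary either from a CSV with header `location_id,name` or
#' from a JSON object mapping IDs to names. Duplicate IDs and malformed rows
#' are rejected with informative errors.
#'
#' @param path Path to a `.csv` or `.json` vocabulary file.
#' @return A [BodyMap-class].
#' @export
loadBodyMap <- function(path) {
  wfAssert(file.exists(path), "body-map file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path)
    ids <- suppressWarnings(as.integer(names(obj)))
    if (anyNA(ids)) stop("non-integer location_id key in ", path, call. = FALSE)
    df <- data.frame(location_id = ids,
                     name = vapply(obj, as.character, character(1)))
  } else {
    raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
    if (!all(c("location_id", "name") %in% names(raw)))
      stop("expected header 'location_id,name' in ", path, call. = FALSE)
    ids <- suppressWarnings(as.integer(raw$location_id))
    if (anyNA(ids)) {
      bad <- which(is.na(ids))[1]
      stop("malformed location_id at data line ", bad, " of ", path,
           call. = FALSE)
    }
    df <- data.frame(location_id = ids, name = raw$name)
  }
  if (anyDuplicated(df$location_id)) {
    dup <- unique(df$location_id[duplicated(df$location_id)])
    stop("duplicate location_id in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  newBodyMap(df)
}

## 1-based one-hot position of each ID: rank in ascending ID order.
bodyMapPositions <- function(map) {
  ids <- sort(map@entries$location_id)
  stats::setNames(seq_along(ids), ids)
}

#' One-hot encode a body-map location
#'
#' Returns a vector of length `bodyMapSize(map)` with a single 1 at the
#' position assigned to `locationId` (its rank among the registered IDs).
#'
#' @param map A [BodyMap-class].
#' @param locationId Registered integer location ID.
#' @return Numeric one-hot vector summing to 1.
#' @examples
#' bm <- canonicalBodyMap()
#' v <- encodeLocation(bm, 135)
#' sum(v); which(v == 1)
#' @export
encodeLocation <- function(map, locationId) {
  pos <- bodyMapPositions(map)
  key <- as.character(as.integer(locationId))
  if (is.na(locationId) || !key %in% names(pos))
    stop("location_id ", locationId, " is not registered in the body map ",
         "(manifest/body-map mismatch)", call. = FALSE)
  v <- numeric(length(pos))
  v[pos[[key]]] <- 1
  v
}

#' Decode a one-hot location encoding
#'
#' Inverse of [encodeLocation()]: maps the argmax position back to the
#' location ID.
#'
#' @param map A [BodyMap-class].
#' @param encoding Numeric vector of length `bodyMapSize(map)`.
#' @return The integer location ID.
#' @export
decodeLocation <- function(map, encoding) {
  wfAssert(length(encoding) == bodyMapSize(map),
           "encoding length does not match body-map size")
  ids <- sort(map@entries$location_id)
  ids[which.max(encoding)]
}

#' Align manifest records with location encodings
#'
#' Produces one one-hot column per manifest record, in manifest order, so
#' that record i's encoding sits at column i (the index-based image-location
#' synchronisation the model relies on).
#'
#' @param manifest A [WoundManifest-class]; every record must carry a
#'   registered location ID.
#' @param map A [BodyMap-class].
#' @return Numeric matrix of dim (bodyMapSize(map), nrecords); zero columns
#'   for an empty manifest.
#' @export
alignLocations <- function(manifest, map) {
  r <- manifestRecords(manifest)
  n <- nrow(r)
  out <- matrix(0, bodyMapSize(map), n)
  if (n == 0L) return(out)
  if (anyNA(r$location_id)) {
    bad <- which(is.na(r$location_id))
    stop("records ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "",
         " have no location_id but the location branch requires one ",
         "(configuration error)", call. = FALSE)
  }
  pos <- bodyMapPositions(map)
  key <- as.character(as.integer(r$location_id))
  miss <- !key %in% names(pos)
  if (any(miss))
    stop("location_id not registered in body map: ",
         paste(unique(r$location_id[miss]), collapse = ", "), call. = FALSE)
  out[cbind(unname(pos[key]), seq_len(n))] <- 1
  out
}
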