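#' Dataset manifest
#'
#' An ordered collection of labeled samples: one row per image with its valve
#' bounding box, binary calcification label, optional split assignment, and
#' augmentation provenance.  Augmented variants are stored lazily: a row
#' carries the path of its source image plus the technique and parameter that
#' produce the variant, and [loadSample()] applies the transform on demand.
#' Boxes, however, are always stored already co-transformed, so dataset
#' arithmetic and metric computations never touch pixels.
#'
#' Columns of `records`:
#' \describe{
#'   \item{image_id}{unique sample id (`STUDY_000` style for originals).}
#'   \item{path}{PNG path of the source image the row is derived from.}
#'   \item{calcified}{logical label.}
#'   \item{x_min, y_min, x_max, y_max}{valve box (0-based half-open); NA when
#'     unannotated.}
#'   \item{width, height}{pixel extent of the (possibly transformed) image;
#'     NA when unknown.}
#'   \item{group}{id of the originating sample; augmentation variants and
#'     duplicates share their original's group, which split utilities can
#'     keep together.}
#'   \item{technique, param}{lazy augmentation transform (`NA` for
#'     originals): one of `translation`, `zoom`, `rotation`, `gamma` and its
#'     parameter value.}
#'   \item{duplicate_of}{id of the duplicated sample for rows added by
#'     [balanceByDuplication()]; NA otherwise.}
#'   \item{split}{`train`/`val`/`test` once assigned, else NA.}
#' }
#'
#' @slot records A `data.frame` with the columns above.
#' @param records A data.frame; missing optional columns are added.
#' @return An `EchoManifest`.
#' @aliases EchoManifest-class
#' @exportClass EchoManifest
setClass("EchoManifest", representation(records = "data.frame"))

.manifestCols <- c("image_id", "path", "calcified",
                   "x_min", "y_min", "x_max", "y_max", "width", "height",
                   "group", "technique", "param", "duplicate_of", "split")

setValidity("EchoManifest", function(object) {
  r <- object@records
  missing <- setdiff(.manifestCols, names(r))
  if (length(missing))
    return(paste("missing manifest columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(r$image_id)) return("image_id values must be unique")
  ok <- is.na(r$x_min) | (r$x_min < r$x_max & r$y_min < r$y_max)
  if (!all(ok)) return("inverted bounding-box coordinates in manifest")
  TRUE
})

#' @rdname EchoManifest-class
#' @export
EchoManifest <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!nrow(records) && !length(records)) {
    records <- data.frame(image_id = character(), path = character(),
                          calcified = logical(), x_min = integer(),
                          y_min = integer(), x_max = integer(),
                          y_max = integer(), stringsAsFactors = FALSE)
  }
  if (is.null(records$group)) records$group <- records$image_id
  for (col in c("width", "height"))
    if (is.null(records[[col]])) records[[col]] <- NA_integer_
  for (col in c("technique", "duplicate_of", "split"))
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  if (is.null(records$param)) records$param <- NA_real_
  rownames(records) <- NULL
  new("EchoManifest", records = records[, .manifestCols])
}

#' @rdname EchoManifest-class
#' @param object,x An `EchoManifest`.
#' @export
manifestRecords <- function(x) x@records

#' @rdname EchoManifest-class
#' @export
nSamples <- function(x) nrow(x@records)

setMethod("length", "EchoManifest", function(x) nrow(x@records))

setMethod("show", "EchoManifest", function(object) {
  r <- object@records
  cat(sprintf("EchoManifest with %d samples (%d calcified / %d not)\n",
              nrow(r), sum(r$calcified), sum(!r$calcified)))
  naug <- sum(!is.na(r$technique))
  ndup <- sum(!is.na(r$duplicate_of))
  if (naug || ndup)
    cat(sprintf("  %d augmented variants, %d balancing duplicates\n",
                naug, ndup))
  if (any(!is.na(r$split)))
    print(table(split = r$split, useNA = "ifany"))
})

#' @rdname EchoManifest-class
#' @param i Row indices (integer, logical, or image ids).
#' @param j,drop,... Ignored (present for the `[` generic).
#' @export
setMethod("[", "EchoManifest", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@records$image_id)
  EchoManifest(x@records[i, , drop = FALSE])
})

## Box of row i, or NULL when unannotated.
.recordBox <- function(rec) {
  if (is.na(rec$x_min)) return(NULL)
  BoundingBox(rec$x_min, rec$y_min, rec$x_max, rec$y_max)
}

#' Materialize one manifest sample
#'
#' Reads the row's source image and applies its stored augmentation
#' transform, if any, returning pixels consistent with the stored box.
#'
#' @param manifest An `EchoManifest`.
#' @param i Row index or image id.
#' @return A list with elements `image`, `box` (`BoundingBox` or NULL),
#'   `calcified`, and `image_id`.
#' @export
loadSample <- function(manifest, i) {
  r <- manifestRecords(manifest)
  if (is.character(i)) i <- match(i, r$image_id)
  rec <- r[i, ]
  img <- readEchoImage(rec$path)
  if (!is.na(rec$technique)) {
    img <- switch(rec$technique,
      translation = translateImage(img, NULL, rec$param)$image,
      zoom        = zoomImage(img, NULL, rec$param)$image,
      rotation    = rotateImage(img, NULL, rec$param)$image,
      gamma       = gammaContrast(img, NULL, rec$param)$image,
      .stopWith("ConfigError", "unknown technique '%s'", rec$technique))
  }
  list(image = img, box = .recordBox(rec),
       calcified = rec$calcified, image_id = rec$image_id)
}
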