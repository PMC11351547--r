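#' Result of a calcification classification
#'
#' @slot probability Probability (or score fraction) of calcification,
#'   in `[0, 1]`.
#' @slot label TRUE when `probability >= cutoff` (the `>=` convention, so a
#'   constant 0.5 model calls every image positive at the default cutoff).
#' @slot cutoff The decision cutoff applied.
#' @aliases ClassificationResult-class
#' @exportClass ClassificationResult
setClass("ClassificationResult", representation(
  probability = "numeric", label = "logical", cutoff = "numeric"))

setValidity("ClassificationResult", function(object) {
  if (object@probability < 0 || object@probability > 1)
    return("probability must be in [0, 1]")
  if (!identical(object@label, object@probability >= object@cutoff))
    return("label inconsistent with cutoff")
  TRUE
})

ClassificationResult <- function(probability, cutoff = 0.5) {
  new("ClassificationResult", probability = probability,
      label = probability >= cutoff, cutoff = cutoff)
}

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult: %s (p = %.3f, cutoff %.2f)\n",
              if (object@label) "calcified" else "not calcified",
              object@probability, object@cutoff))
})

#' @rdname ClassificationResult-class
#' @param object A `ClassificationResult`.
#' @export
isCalcified <- function(object) object@label

#' @rdname ClassificationResult-class
#' @export
calcifiedProbability <- function(object) object@probability

#' Threshold binarization of an echo image
#'
#' Sets every pixel strictly brighter than `threshold` (in all channels) to
#' pure white (255) and every other pixel to black (0).  With the thresholds
#' used for calcium screening (190-220), only near-white hyperechoic
#' structures survive.
#'
#' @param image 8-bit image array; for RGB input a pixel is white only when
#'   its minimum channel exceeds the threshold.
#' @param threshold Gray level in `[0, 255]`; the comparison is strict, so a
#'   pixel exactly at the threshold turns black.
#' @return A binary image of the same shape with values in `{0, 255}`.
#' @examples
#' heuristicBinarize(matrix(c(0, 220, 221), 1), 220)  # 0 0 255
#' @export
heuristicBinarize <- function(image, threshold) {
  .assert(threshold >= 0 && threshold <= 255, "ValueError",
          "threshold must be in [0, 255]")
  white <- .channelMin(image) > threshold
  out <- .perChannel(image * 0, function(m) m)
  .perChannel(out, function(m) { m[white] <- 255; m })
}

#' Heuristic calcium call from white pixels
#'
#' Binarizes the image at `threshold` and declares the valve calcified if at
#' least one white pixel remains.  The probability reported is the white
#' pixel fraction, a convenience score; the label depends only on whether
#' any white pixel exists.
#'
#' @inheritParams heuristicBinarize
#' @return A [ClassificationResult-class].
#' @examples
#' img <- matrix(160, 32, 32); img[16, 16] <- 255
#' isCalcified(heuristicClassify(img, 220))  # TRUE
#' @export
heuristicClassify <- function(image, threshold) {
  white <- .channelMin(image) > threshold
  frac <- mean(white)
  new("ClassificationResult", probability = frac, label = any(white),
      cutoff = 1 / (length(white) + 1))
}
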