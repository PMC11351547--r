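#' Axis-aligned bounding box
#'
#' A rectangle in 0-based, half-open pixel coordinates: the box covers columns
#' `[xmin, xmax)` and rows `[ymin, ymax)`, so its width is exactly
#' `xmax - xmin`.  Used both for manual valve annotations and for detector
#' output.
#'
#' @slot xmin,ymin,xmax,ymax Integer pixel coordinates, `0 <= xmin < xmax`,
#'   `0 <= ymin < ymax`.
#' @param xmin,ymin,xmax,ymax Corner coordinates (coerced to integer).
#' @return A `BoundingBox` object.
#' @examples
#' b <- BoundingBox(10, 20, 30, 50)
#' boxWidth(b)   # 20
#' boxHeight(b)  # 30
#' @name BoundingBox-class
#' @aliases BoundingBox-class
#' @exportClass BoundingBox
setClass("BoundingBox",
  representation(xmin = "integer", ymin = "integer",
                 xmax = "integer", ymax = "integer"))

setValidity("BoundingBox", function(object) {
  if (length(object@xmin) != 1L || length(object@ymin) != 1L ||
      length(object@xmax) != 1L || length(object@ymax) != 1L)
    return("all corner slots must be length 1")
  if (anyNA(c(object@xmin, object@ymin, object@xmax, object@ymax)))
    return("corner coordinates must not be NA")
  if (object@xmin < 0L || object@ymin < 0L)
    return("xmin and ymin must be >= 0")
  if (object@xmax <= object@xmin) return("xmax must be > xmin")
  if (object@ymax <= object@ymin) return("ymax must be > ymin")
  TRUE
})

#' @rdname BoundingBox-class
#' @export
BoundingBox <- function(xmin, ymin, xmax, ymax) {
  new("BoundingBox",
      xmin = as.integer(round(xmin)), ymin = as.integer(round(ymin)),
      xmax = as.integer(round(xmax)), ymax = as.integer(round(ymax)))
}

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox [%d, %d) x [%d, %d)  (%d x %d px)\n",
              object@xmin, object@xmax, object@ymin, object@ymax,
              boxWidth(object), boxHeight(object)))
})

#' @rdname BoundingBox-class
#' @param box A `BoundingBox`.
#' @export
boxWidth <- function(box) box@xmax - box@xmin

#' @rdname BoundingBox-class
#' @export
boxHeight <- function(box) box@ymax - box@ymin

#' @rdname BoundingBox-class
#' @export
boxArea <- function(box) as.numeric(boxWidth(box)) * boxHeight(box)

#' @rdname BoundingBox-class
#' @export
boxCenter <- function(box) {
  c(x = (box@xmin + box@xmax) / 2, y = (box@ymin + box@ymax) / 2)
}

## Clip raw (possibly out-of-range) coordinates to a w x h image extent;
## NULL if nothing remains.  Works on plain numbers so callers can clip
## candidate boxes that would be invalid BoundingBox objects.
.clipRawBox <- function(xmin, ymin, xmax, ymax, w, h) {
  xmin <- max(xmin, 0L); ymin <- max(ymin, 0L)
  xmax <- min(xmax, as.integer(w)); ymax <- min(ymax, as.integer(h))
  if (xmax <= xmin || ymax <= ymin) return(NULL)
  BoundingBox(xmin, ymin, xmax, ymax)
}

## Clip a box to a w x h image extent; NULL if nothing remains.
.clipBox <- function(box, w, h) {
  .clipRawBox(box@xmin, box@ymin, box@xmax, box@ymax, w, h)
}

## Box from a vector c(xmin, ymin, xmax, ymax).
.boxFromVec <- function(v) BoundingBox(v[1L], v[2L], v[3L], v[4L])

.boxToVec <- function(box) {
  c(xmin = box@xmin, ymin = box@ymin, xmax = box@xmax, ymax = box@ymax)
}

#' Intersection over union of two boxes
#'
#' Overlap ratio under half-open pixel semantics: the area of the
#' intersection rectangle divided by the area of the union.  Used to decide
#' whether a detected valve box counts as a correct detection.
#'
#' @param a,b `BoundingBox` objects.
#' @return A number in `[0, 1]`; 1 for identical boxes, 0 for disjoint ones.
#' @examples
#' iou(BoundingBox(0, 0, 2, 2), BoundingBox(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(a, b) {
  ix <- max(0L, min(a@xmax, b@xmax) - max(a@xmin, b@xmin))
  iy <- max(0L, min(a@ymax, b@ymax) - max(a@ymin, b@ymin))
  inter <- as.numeric(ix) * iy
  if (inter == 0) return(0)
  inter / (boxArea(a) + boxArea(b) - inter)
}

#' Crop the region of interest inside a box
#'
#' Returns the sub-image covered by `box`; output pixel (0, 0) is input pixel
#' `(xmin, ymin)`.  This is the step that hands the valve region to the
#' calcification classifier.
#'
#' @param image Image array (matrix or H x W x 3).
#' @param box A `BoundingBox` lying fully inside the image.
#' @return The cropped image, of size `boxHeight(box)` x `boxWidth(box)`.
#' @examples
#' img <- matrix(seq_len(100 * 80), 80, 100)
#' dim(cropRoi(img, BoundingBox(10, 20, 30, 50)))  # 30 x 20
#' @export
cropRoi <- function(image, box) {
  d <- .imageDim(image)
  .assert(box@xmax <= d["w"] && box@ymax <= d["h"], "BoundsError",
          "box [%d,%d)x[%d,%d) exceeds the %d x %d image",
          box@xmin, box@xmax, box@ymin, box@ymax, d["w"], d["h"])
  rows <- (box@ymin + 1L):box@ymax
  cols <- (box@xmin + 1L):box@xmax
  if (is.matrix(image)) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}

#' Convert a box to and from the detector's normalized record
#'
#' The detector's training files store one object per line as
#' `class cx cy w h`, all normalized to `[0, 1]` by the image extent.
#' `toDetectorRecord` produces that record (class 0, the single
#' "aortic_valve" class); `fromDetectorRecord` inverts it, recovering the box
#' to within one pixel.
#'
#' @param box A `BoundingBox`.
#' @param imageW,imageH Image extent in pixels.
#' @param record Numeric vector `c(class, cx, cy, w, h)`.
#' @return `toDetectorRecord`: numeric vector `c(class, cx, cy, w, h)`;
#'   `fromDetectorRecord`: a `BoundingBox`.
#' @examples
#' toDetectorRecord(BoundingBox(160, 160, 480, 480), 640, 640)
#' @export
toDetectorRecord <- function(box, imageW, imageH) {
  c(class = 0,
    cx = (box@xmin + box@xmax) / (2 * imageW),
    cy = (box@ymin + box@ymax) / (2 * imageH),
    w = boxWidth(box) / imageW,
    h = boxHeight(box) / imageH)
}

#' @rdname toDetectorRecord
#' @export
fromDetectorRecord <- function(record, imageW, imageH) {
  cx <- record[[2L]] * imageW; cy <- record[[3L]] * imageH
  w <- record[[4L]] * imageW; h <- record[[5L]] * imageH
  BoundingBox(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}
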