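#' Ultrasound sector (cone) mask
#'
#' The wedge-shaped imaging field recovered from an echo frame: a binary
#' raster plus the fitted boundary parameters (apex position, the angles of
#' the two straight edges measured from the downward axis, and the far-arc
#' radius).  When the two-lines-plus-arc fit fails, [detectCone()] falls back
#' to the convex hull of the largest bright region and sets `fallback`.
#'
#' @slot mask Logical matrix, same size as the source image.
#' @slot apex `(x, y)` fitted apex position (pixel-center coordinates).
#' @slot edgeAngles Two angles in degrees from the downward axis (left edge
#'   negative, right edge positive); `NA` on the fallback path.
#' @slot radius Far-arc radius in pixels from the apex; `NA` on fallback.
#' @slot fallback TRUE when the parametric fit was rejected and the convex
#'   hull was used instead.
#' @aliases ConeMask-class
#' @exportClass ConeMask
setClass("ConeMask", representation(
  mask = "matrix", apex = "numeric", edgeAngles = "numeric",
  radius = "numeric", fallback = "logical"))

setValidity("ConeMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (!any(object@mask)) return("mask must contain foreground")
  TRUE
})

setMethod("show", "ConeMask", function(object) {
  cat(sprintf("ConeMask %d x %d, %d px foreground", ncol(object@mask),
              nrow(object@mask), sum(object@mask)))
  if (object@fallback) {
    cat("  [convex-hull fallback]\n")
  } else {
    cat(sprintf(", apex (%.1f, %.1f), edges %.1f / %.1f deg, radius %.0f\n",
                object@apex[1L], object@apex[2L], object@edgeAngles[1L],
                object@edgeAngles[2L], object@radius))
  }
})

#' @rdname ConeMask-class
#' @param object A `ConeMask`.
#' @export
coneMaskRaster <- function(object) object@mask

#' @rdname ConeMask-class
#' @export
usedFallback <- function(object) object@fallback

## Scanline fill of a convex polygon given vertex coordinates
## (pixel-center convention), returning a logical S-row mask.
.fillConvexPolygon <- function(px, py, nrowS, ncolS) {
  mask <- matrix(FALSE, nrowS, ncolS)
  n <- length(px)
  for (r in seq_len(nrowS)) {
    y <- r - 0.5
    xs <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- py[i]; y2 <- py[j]
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        t <- (y - y1) / (y2 - y1)
        xs <- c(xs, px[i] + t * (px[j] - px[i]))
      }
    }
    if (length(xs) >= 2L) {
      lo <- max(1L, ceiling(min(xs) + 0.5))
      hi <- min(ncolS, floor(max(xs) + 0.5))
      if (hi >= lo) mask[r, lo:hi] <- TRUE
    }
  }
  mask
}

## Rasterize a fitted sector (apex + edge angles in degrees + radius).
.rasterSector <- function(apex, angles, radius, nrowS, ncolS) {
  g <- .pixelGrid(max(nrowS, ncolS))
  gx <- g$x[seq_len(nrowS), seq_len(ncolS)]
  gy <- g$y[seq_len(nrowS), seq_len(ncolS)]
  dx <- gx - apex[1L]; dy <- gy - apex[2L]
  r <- sqrt(dx^2 + dy^2)
  ## signed angle from the downward axis, left negative
  th <- atan2(dx, dy) * 180 / pi
  m <- r <= radius & th >= angles[1L] & th <= angles[2L]
  dim(m) <- c(nrowS, ncolS)
  m
}

.maskIoU <- function(a, b) sum(a & b) / sum(a | b)

#' Detect the ultrasound sector in an echo frame
#'
#' Recovers the cone-shaped imaging field: foreground pixels (brighter than
#' `bgThreshold`) are reduced to their largest connected component, the left
#' and right boundaries are fitted as straight lines over the upper straight
#' part of the sector, their intersection gives the apex, and the far arc
#' radius is taken from the foreground's extent.  The fitted sector is
#' rasterized as the mask; if it disagrees with the observed foreground
#' (IoU below `minFitIoU`), the convex hull of the foreground is used
#' instead and the result is flagged as a fallback.
#'
#' @param image 8-bit image with a dark exterior and a brighter sector.
#' @param bgThreshold Gray level separating background from sector interior
#'   (default 10).
#' @param minFitIoU Minimum mask-vs-foreground IoU for accepting the
#'   parametric fit (default 0.8).
#' @return A [ConeMask-class] object.  Signals a `DetectionError` when the
#'   image has no foreground at all.
#' @examples
#' sc <- generateScene(SceneParams(imageSize = 256, speckleSD = 0))
#' cm <- detectCone(sc$image)
#' usedFallback(cm)
#' @export
detectCone <- function(image, bgThreshold = 10, minFitIoU = 0.8) {
  gray <- .asGray(image)
  fg <- gray > bgThreshold
  .assert(any(fg), "DetectionError", "no foreground above gray level %s",
          format(bgThreshold))
  lab <- EBImage::bwlabel(fg * 1)
  labels <- tabulate(lab[lab > 0])
  fg <- lab == which.max(labels)
  nr <- nrow(fg); nc <- ncol(fg)

  ## left/right boundary pixel centers per row
  rows <- which(rowSums(fg) > 0L)
  xl <- vapply(rows, function(r) which(fg[r, ])[1L] - 0.5, numeric(1L))
  xr <- vapply(rows, function(r) {
    w <- which(fg[r, ]); w[length(w)] - 0.5
  }, numeric(1L))
  ys <- rows - 0.5

  ## fit the straight edges over the upper straight part of the sector
  yTop <- min(ys); yBot <- max(ys)
  sel <- ys >= yTop + 0.12 * (yBot - yTop) & ys <= yTop + 0.6 * (yBot - yTop)
  fallbackMask <- function() {
    idx <- which(fg, arr.ind = TRUE)
    pts <- cbind(idx[, 2L] - 0.5, idx[, 1L] - 0.5)  # (x, y)
    h <- grDevices::chull(pts)
    mask <- .fillConvexPolygon(pts[h, 1L], pts[h, 2L], nr, nc)
    new("ConeMask", mask = mask | fg, apex = c(NA_real_, NA_real_),
        edgeAngles = c(NA_real_, NA_real_), radius = NA_real_,
        fallback = TRUE)
  }
  if (sum(sel) < 5L) return(fallbackMask())

  fitL <- lm(xl[sel] ~ ys[sel])
  fitR <- lm(xr[sel] ~ ys[sel])
  a1 <- coef(fitL)[[1L]]; b1 <- coef(fitL)[[2L]]
  a2 <- coef(fitR)[[1L]]; b2 <- coef(fitR)[[2L]]
  if (!is.finite(b1) || !is.finite(b2) || abs(b2 - b1) < 1e-6)
    return(fallbackMask())
  yApex <- (a1 - a2) / (b2 - b1)
  xApex <- a1 + b1 * yApex
  apex <- c(xApex, yApex)

  idx <- which(fg, arr.ind = TRUE)
  d <- sqrt((idx[, 2L] - 0.5 - apex[1L])^2 + (idx[, 1L] - 0.5 - apex[2L])^2)
  radius <- as.numeric(quantile(d, 0.999))
  angles <- sort(c(atan(b1), atan(b2)) * 180 / pi)

  sector <- .rasterSector(apex, angles, radius, nr, nc)
  if (!any(sector) || .maskIoU(sector, fg) < minFitIoU) return(fallbackMask())
  new("ConeMask", mask = sector, apex = apex, edgeAngles = angles,
      radius = radius, fallback = FALSE)
}

#' Mask the sector and crop away the surrounding black border
#'
#' Sets every pixel outside the cone mask to 0 and crops the image to the
#' tight bounding box of the mask, minimizing the unnecessary black areas
#' around the sector.
#'
#' @param image Image array.
#' @param mask A [ConeMask-class] (or a logical matrix) of the same size.
#' @return A list with `image` (the masked, cropped image) and `offset`,
#'   the `(x, y)` position of the output's origin in the input frame, so
#'   boxes map into the crop by subtracting it.
#' @export
maskAndTightCrop <- function(image, mask) {
  if (is(mask, "ConeMask")) mask <- coneMaskRaster(mask)
  d <- .imageDim(image)
  stopifnot(nrow(mask) == d["h"], ncol(mask) == d["w"])
  image <- .perChannel(image, function(m) { m[!mask] <- 0; m })
  idx <- which(mask, arr.ind = TRUE)
  r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
  c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
  out <- if (is.matrix(image)) image[r0:r1, c0:c1, drop = FALSE]
         else image[r0:r1, c0:c1, , drop = FALSE]
  list(image = out, offset = c(x = c0 - 1L, y = r0 - 1L))
}

#' Standardize an image to a fixed square window without rescaling
#'
#' Extracts a `size` x `size` window around the foreground centroid (or the
#' center of `boxHint` when given) with no resampling, padding with zeros
#' where the source is smaller than the window.  Keeping pixels 1:1 avoids
#' the aspect-ratio deformation that automatic resizing would introduce.
#'
#' @param image Image array.
#' @param boxHint Optional `BoundingBox` whose center the window should
#'   contain (e.g. a valve annotation); default centers on the centroid of
#'   the nonzero pixels.
#' @param size Window side in pixels (default 640).
#' @param windowCenter Optional `(x, y)` override of the window center.
#' @return A list with `image` (`size` x `size`) and `offset`, the `(x, y)`
#'   of the window origin in the source frame (possibly negative when
#'   padding); a source box maps into the window as `box - offset`.
#' @export
standardizeCrop <- function(image, boxHint = NULL, size = 640,
                            windowCenter = NULL) {
  d <- .imageDim(image)
  h <- as.integer(d["h"]); w <- as.integer(d["w"])
  ctr <- if (!is.null(windowCenter)) {
    as.numeric(windowCenter)
  } else if (!is.null(boxHint)) {
    boxCenter(boxHint)
  } else {
    gray <- .asGray(image)
    if (any(gray > 0)) {
      idx <- which(gray > 0, arr.ind = TRUE)
      c(mean(idx[, 2L]) - 0.5, mean(idx[, 1L]) - 0.5)
    } else c(w / 2, h / 2)
  }
  clampOrigin <- function(c0, extent) {
    o <- round(c0 - size / 2)
    max(min(o, max(0L, extent - size)), min(0L, extent - size))
  }
  x0 <- clampOrigin(ctr[1L], w)
  y0 <- clampOrigin(ctr[2L], h)

  takeWindow <- function(m) {
    out <- matrix(0, size, size)
    srcRows <- max(1L, y0 + 1L):min(h, y0 + size)
    srcCols <- max(1L, x0 + 1L):min(w, x0 + size)
    out[srcRows - y0, srcCols - x0] <- m[srcRows, srcCols]
    out
  }
  list(image = .perChannel(image, takeWindow),
       offset = c(x = as.integer(x0), y = as.integer(y0)))
}

#' Background noise reduction by global minimum subtraction
#'
#' Subtracts the global minimum pixel value (a single scalar over all pixels
#' and channels) from the whole image, turning the darkest zones into pure
#' black.  Idempotent: the output's minimum is always 0.
#'
#' @param image 8-bit image array.
#' @return The shifted image, same shape, minimum exactly 0.
#' @examples
#' reduceNoise(matrix(c(10, 200, 255), 1))  # 0 190 245
#' @export
reduceNoise <- function(image) {
  pmax(image - min(image), 0)
}
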