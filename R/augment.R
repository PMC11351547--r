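## Box-aware augmentation operators.  Pixel-center convention: pixel (x, y)
## (0-based) has its center at (x + 0.5, y + 0.5); the image center used by
## zoom and rotation is (W/2, H/2).  All warps keep the canvas size fixed,
## fill vacated areas with 0, and use bilinear interpolation.

## Bilinear sample of a matrix at continuous (x, y); 0 outside the extent.
.bilinearSample <- function(m, x, y) {
  u <- x - 0.5; v <- y - 0.5
  x0 <- floor(u); y0 <- floor(v)
  fx <- u - x0; fy <- v - y0
  H <- nrow(m); W <- ncol(m)
  px <- function(xx, yy) {
    ok <- xx >= 0 & xx <= W - 1 & yy >= 0 & yy <= H - 1
    out <- numeric(length(xx))
    out[ok] <- m[cbind(yy[ok] + 1, xx[ok] + 1)]
    out
  }
  (1 - fy) * ((1 - fx) * px(x0, y0) + fx * px(x0 + 1, y0)) +
    fy * ((1 - fx) * px(x0, y0 + 1) + fx * px(x0 + 1, y0 + 1))
}

## Warp one channel given the inverse map (output center -> input center).
.warpChannel <- function(m, invMap) {
  H <- nrow(m); W <- ncol(m)
  ox <- rep(seq_len(W) - 0.5, each = H)
  oy <- rep(seq_len(H) - 0.5, times = W)
  q <- invMap(ox, oy)
  out <- .bilinearSample(m, q$x, q$y)
  matrix(pmin(255, pmax(0, round(out))), H, W)
}

.transformedBox <- function(corners, w, h, id = NULL) {
  clipped <- .clipRawBox(floor(min(corners[, 1L])), floor(min(corners[, 2L])),
                         ceiling(max(corners[, 1L])),
                         ceiling(max(corners[, 2L])), w, h)
  .assert(!is.null(clipped), "BoxLostError",
          "bounding box%s left the canvas under the transform",
          if (is.null(id)) "" else paste0(" of ", id))
  clipped
}

.boxCorners <- function(box) {
  cbind(x = c(box@xmin, box@xmax, box@xmin, box@xmax),
        y = c(box@ymin, box@ymin, box@ymax, box@ymax))
}

#' Box-aware augmentation operators
#'
#' The four image transformations used to enlarge the dataset, each applied
#' with the fixed parameter pairs of [augmentDataset()] and co-transforming
#' the valve bounding box:
#' \describe{
#'   \item{`translateImage`}{shifts by `round(fraction * W)` horizontally and
#'     `round(fraction * H)` vertically (the same signed fraction on both
#'     axes), filling vacated pixels with 0.}
#'   \item{`zoomImage`}{scales about the image center with the canvas size
#'     fixed, so shrinking pads with black and enlarging crops.}
#'   \item{`rotateImage`}{rotates about the image center (positive angles
#'     turn clockwise on screen, i.e. counterclockwise in the y-down pixel
#'     frame), canvas fixed, bilinear interpolation; the new box is the
#'     axis-aligned bounding box of the four rotated corners.}
#'   \item{`gammaContrast`}{the power-law point operation
#'     `round(255 * (v/255)^gamma)`; the box is unchanged.}
#' }
#' Shifted/mapped boxes are clipped to the canvas; a `BoxLostError` is
#' signalled when nothing of the box remains.
#'
#' @param image 8-bit image array (matrix or H x W x 3).
#' @param box A `BoundingBox`, or NULL when only pixels are needed.
#' @param fraction Signed translation fraction, `|fraction| < 1`.
#' @param scale Zoom factor, `> 0`.
#' @param angle Rotation angle in degrees, `|angle| <= 45`.
#' @param gamma Gamma exponent, `> 0`.
#' @return A list with the transformed `image` and `box`.
#' @examples
#' img <- generateScene(SceneParams(imageSize = 128, speckleSD = 0))$image
#' r <- rotateImage(img, BoundingBox(40, 40, 90, 90), 10)
#' r$box
#' @name augmentOps
NULL

#' @rdname augmentOps
#' @export
translateImage <- function(image, box, fraction) {
  .assert(abs(fraction) < 1, "ValueError", "|fraction| must be < 1")
  d <- .imageDim(image)
  dx <- as.integer(round(fraction * d["w"]))
  dy <- as.integer(round(fraction * d["h"]))
  shift <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    srcRows <- intersect(seq_len(nrow(m)), seq_len(nrow(m)) - dy)
    srcCols <- intersect(seq_len(ncol(m)), seq_len(ncol(m)) - dx)
    out[srcRows + dy, srcCols + dx] <- m[srcRows, srcCols]
    out
  }
  newBox <- NULL
  if (!is.null(box)) {
    newBox <- .clipRawBox(box@xmin + dx, box@ymin + dy,
                          box@xmax + dx, box@ymax + dy, d["w"], d["h"])
    .assert(!is.null(newBox), "BoxLostError",
            "translated box left the canvas")
  }
  list(image = .perChannel(image, shift), box = newBox)
}

#' @rdname augmentOps
#' @export
zoomImage <- function(image, box, scale) {
  .assert(scale > 0, "ValueError", "scale must be > 0")
  d <- .imageDim(image)
  cx <- d[["w"]] / 2; cy <- d[["h"]] / 2
  invMap <- function(x, y) list(x = cx + (x - cx) / scale,
                                y = cy + (y - cy) / scale)
  newBox <- NULL
  if (!is.null(box)) {
    cc <- .boxCorners(box)
    cc[, 1L] <- cx + (cc[, 1L] - cx) * scale
    cc[, 2L] <- cy + (cc[, 2L] - cy) * scale
    newBox <- .transformedBox(cc, d["w"], d["h"])
  }
  list(image = .perChannel(image, function(m) .warpChannel(m, invMap)),
       box = newBox)
}

#' @rdname augmentOps
#' @export
rotateImage <- function(image, box, angle) {
  .assert(abs(angle) <= 45, "ValueError", "|angle| must be <= 45 degrees")
  d <- .imageDim(image)
  cx <- d[["w"]] / 2; cy <- d[["h"]] / 2
  th <- angle * pi / 180
  invMap <- function(x, y) {
    dx <- x - cx; dy <- y - cy
    list(x = cx + cos(th) * dx + sin(th) * dy,
         y = cy - sin(th) * dx + cos(th) * dy)
  }
  newBox <- NULL
  if (!is.null(box)) {
    cc <- .boxCorners(box)
    dx <- cc[, 1L] - cx; dy <- cc[, 2L] - cy
    fwd <- cbind(cx + cos(th) * dx - sin(th) * dy,
                 cy + sin(th) * dx + cos(th) * dy)
    newBox <- .transformedBox(fwd, d["w"], d["h"])
  }
  list(image = .perChannel(image, function(m) .warpChannel(m, invMap)),
       box = newBox)
}

#' @rdname augmentOps
#' @export
gammaContrast <- function(image, box, gamma) {
  .assert(gamma > 0, "ValueError", "gamma must be > 0")
  lut <- round(255 * ((0:255) / 255)^gamma)
  list(image = .perChannel(image, function(m) {
    out <- lut[pmin(255, pmax(0, round(m))) + 1L]
    matrix(out, nrow(m), ncol(m))
  }), box = box)
}

## Fixed parameter pairs: each technique contributes exactly two variants.
.fixedAugmentParams <- list(translation = c(0.2, -0.2),
                     zoom = c(0.5, 2),
                     rotation = c(10, -10),
                     gamma = c(0.5, 1.2))

.paramTag <- function(technique, p) {
  prefix <- c(translation = "tr", zoom = "zm", rotation = "rot",
              gamma = "gm")[[technique]]
  paste0(prefix, gsub("-", "m", gsub("\\.", "p", format(p))))
}

## Transform one record's box analytically for a technique variant.
.transformRecordBox <- function(rec, technique, p) {
  if (is.na(rec$x_min)) return(rec[c("x_min", "y_min", "x_max", "y_max")])
  w <- rec$width; h <- rec$height
  .assert(!is.na(w) && !is.na(h), "ValueError",
          "record %s has no image size; cannot co-transform its box",
          rec$image_id)
  box <- BoundingBox(rec$x_min, rec$y_min, rec$x_max, rec$y_max)
  out <- switch(technique,
      translation = {
        dx <- as.integer(round(p * w)); dy <- as.integer(round(p * h))
        nb <- .clipRawBox(box@xmin + dx, box@ymin + dy,
                          box@xmax + dx, box@ymax + dy, w, h)
        .assert(!is.null(nb), "BoxLostError",
                "bounding box of %s left the canvas", rec$image_id)
        nb
      },
      zoom = {
        cc <- .boxCorners(box)
        cc[, 1L] <- w / 2 + (cc[, 1L] - w / 2) * p
        cc[, 2L] <- h / 2 + (cc[, 2L] - h / 2) * p
        .transformedBox(cc, w, h, rec$image_id)
      },
      rotation = {
        th <- p * pi / 180
        cc <- .boxCorners(box)
        dx <- cc[, 1L] - w / 2; dy <- cc[, 2L] - h / 2
        fwd <- cbind(w / 2 + cos(th) * dx - sin(th) * dy,
                     h / 2 + sin(th) * dx + cos(th) * dy)
        .transformedBox(fwd, w, h, rec$image_id)
      },
      gamma = box,
      .stopWith("ConfigError", "unknown technique '%s'", technique))
  data.frame(x_min = out@xmin, y_min = out@ymin,
             x_max = out@xmax, y_max = out@ymax)
}

#' Expand a dataset with fixed-parameter augmentation variants
#'
#' For every record and every requested technique, adds the two variants of
#' that technique's fixed parameter pair (translation +0.2/-0.2 of the
#' extent on both axes, zoom 0.5/2, rotation +10/-10 degrees, gamma 0.5/1.2),
#' so the output holds `n * (1 + 2 * length(techniques))` records.  Variant
#' boxes are co-transformed analytically; variant pixels stay lazy (the
#' technique and parameter are stored and applied by [loadSample()]).
#'
#' @param manifest A non-empty `EchoManifest`.
#' @param techniques Character subset of
#'   `c("translation", "zoom", "rotation", "gamma")`.
#' @param params Parameter pairs per technique; the fixed defaults unless
#'   `custom = TRUE`.
#' @param custom Allow parameter values outside the fixed sets.
#' @return The expanded `EchoManifest`: originals first, then variants
#'   grouped by original (sharing its `group`).
#' @examples
#' \donttest{
#' m <- generateDataset(2, 2, SceneParams(imageSize = 192), seed = 1)
#' nSamples(augmentDataset(m, "rotation"))  # 4 * 3 = 12
#' }
#' @export
augmentDataset <- function(manifest, techniques,
                           params = .fixedAugmentParams[techniques],
                           custom = FALSE) {
  .assert(nSamples(manifest) > 0L, "ValueError", "manifest is empty")
  techniques <- match.arg(techniques, names(.fixedAugmentParams),
                          several.ok = TRUE)
  if (!custom) {
    for (t in techniques)
      .assert(identical(as.numeric(params[[t]]),
                        as.numeric(.fixedAugmentParams[[t]])), "ValueError",
              "non-standard %s parameters require custom = TRUE", t)
  }
  r <- manifestRecords(manifest)
  out <- list(r)
  for (i in seq_len(nrow(r))) {
    rec <- r[i, ]
    .assert(is.na(rec$technique), "ValueError",
            "record %s is already an augmented variant", rec$image_id)
    for (t in techniques) {
      for (p in params[[t]]) {
        v <- rec
        v$image_id <- paste(rec$image_id, .paramTag(t, p), sep = "_")
        v$technique <- t
        v$param <- p
        v[c("x_min", "y_min", "x_max", "y_max")] <-
          .transformRecordBox(rec, t, p)
        out[[length(out) + 1L]] <- v
      }
    }
  }
  EchoManifest(do.call(rbind, out))
}

#' Balance classes by duplicating minority samples
#'
#' Duplicates minority-class records cyclically, in manifest order, until
#' both classes hold the same number of samples; the output therefore has
#' `2 * majority` records.  Duplicates get fresh ids and carry the original
#' id in `duplicate_of` (and share its `group`), so split utilities can keep
#' them out of the test set.
#'
#' @param manifest An `EchoManifest` with both classes present (a
#'   `BalanceError` is signalled otherwise).
#' @return The balanced `EchoManifest`.
#' @export
balanceByDuplication <- function(manifest) {
  r <- manifestRecords(manifest)
  nPos <- sum(r$calcified); nNeg <- sum(!r$calcified)
  .assert(nPos > 0L && nNeg > 0L, "BalanceError",
          "both classes must be present (have %d calcified / %d not)",
          nPos, nNeg)
  if (nPos == nNeg) return(manifest)
  minority <- r[r$calcified == (nPos < nNeg), , drop = FALSE]
  need <- abs(nPos - nNeg)
  src <- minority[((seq_len(need) - 1L) %% nrow(minority)) + 1L, ,
                  drop = FALSE]
  copyN <- ((seq_len(need) - 1L) %/% nrow(minority)) + 1L
  src$duplicate_of <- src$image_id
  src$image_id <- sprintf("%s_dup%d", src$image_id, copyN)
  EchoManifest(rbind(r, src))
}
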