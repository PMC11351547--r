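#' Parameters of a synthetic echocardiogram scene
#'
#' Describes one synthetic parasternal short-axis frame: a dark background, a
#' wedge-shaped ultrasound sector ("cone") opening downward from an apex near
#' the top edge and filled with Gaussian speckle texture, a bright ring
#' standing in for the aortic valve in cross-section, and optional near-white
#' calcium blobs on the ring.  The ring is deliberately schematic rather than
#' anatomical: the pipeline only needs a localizable structure with an exact
#' tight bounding box.
#'
#' Geometry is in pixel units with 0-based coordinates and pixel centers at
#' half-integers; the cone axis points straight down from the apex.  All
#' defaults scale with `imageSize` so the same scene can be generated at any
#' resolution.
#'
#' @slot imageSize Square image side in pixels (default 800).
#' @slot coneApex `(x, y)` apex position near the top edge.
#' @slot coneHalfAngle Sector half-opening angle in degrees (default 35).
#' @slot coneRadius Sector depth in pixels.
#' @slot backgroundLevel Gray level outside the cone (default 0).
#' @slot speckleMean,speckleSD Gaussian speckle parameters inside the cone
#'   (defaults 70 and 25); `speckleSD = 0` gives a noiseless scene.
#' @slot valveCenter `(x, y)` center of the valve ring.
#' @slot valveOuterRadius,valveInnerRadius Ring radii in pixels.
#' @slot valveLevel Gray level of the ring (default 160).
#' @slot calciumBlobs data.frame with columns `x, y, radius, intensity`;
#'   each blob is a Gaussian-profiled disc (sigma = radius / 2) whose peak
#'   equals `intensity` exactly, so threshold behavior is controllable.
#' @slot seed Integer seed; identical parameters and seed give a
#'   bit-identical image.
#' @param imageSize,coneApex,coneHalfAngle,coneRadius,backgroundLevel
#'   See slots; geometric defaults are derived from `imageSize`.
#' @param speckleMean,speckleSD,valveCenter,valveOuterRadius See slots.
#' @param valveInnerRadius,valveLevel,calciumBlobs,seed See slots.
#' @return A `SceneParams` object.
#' @examples
#' p <- SceneParams(imageSize = 320)
#' sc <- generateScene(p)
#' dim(sc$image)
#' @aliases SceneParams-class
#' @exportClass SceneParams
setClass("SceneParams", representation(
  imageSize = "integer", coneApex = "numeric", coneHalfAngle = "numeric",
  coneRadius = "numeric", backgroundLevel = "numeric",
  speckleMean = "numeric", speckleSD = "numeric",
  valveCenter = "numeric", valveOuterRadius = "numeric",
  valveInnerRadius = "numeric", valveLevel = "numeric",
  calciumBlobs = "data.frame", seed = "integer"))

setValidity("SceneParams", function(object) {
  if (object@imageSize < 32L) return("imageSize must be >= 32")
  if (length(object@coneApex) != 2L || length(object@valveCenter) != 2L)
    return("coneApex and valveCenter must be (x, y) pairs")
  if (object@coneHalfAngle <= 0 || object@coneHalfAngle >= 90)
    return("coneHalfAngle must be in (0, 90) degrees")
  if (object@valveInnerRadius >= object@valveOuterRadius)
    return("valveInnerRadius must be < valveOuterRadius")
  if (nrow(object@calciumBlobs) &&
      !all(c("x", "y", "radius", "intensity") %in%
           names(object@calciumBlobs)))
    return("calciumBlobs needs columns x, y, radius, intensity")
  if (nrow(object@calciumBlobs) &&
      (any(object@calciumBlobs$intensity < 0) ||
       any(object@calciumBlobs$intensity > 255)))
    return("blob intensity must be in 0-255")
  TRUE
})

#' @rdname SceneParams-class
#' @export
SceneParams <- function(imageSize = 800,
                        coneApex = c(0.5, 0.04) * imageSize,
                        coneHalfAngle = 35,
                        coneRadius = 0.85 * imageSize,
                        backgroundLevel = 0,
                        speckleMean = 70, speckleSD = 25,
                        valveCenter = c(coneApex[1L],
                                        coneApex[2L] + 0.55 * coneRadius),
                        valveOuterRadius = 0.09 * imageSize,
                        valveInnerRadius = 0.06 * imageSize,
                        valveLevel = 160,
                        calciumBlobs = data.frame(),
                        seed = 0L) {
  if (nrow(calciumBlobs) == 0L)
    calciumBlobs <- data.frame(x = numeric(), y = numeric(),
                               radius = numeric(), intensity = numeric())
  new("SceneParams", imageSize = as.integer(imageSize),
      coneApex = as.numeric(coneApex), coneHalfAngle = coneHalfAngle,
      coneRadius = coneRadius, backgroundLevel = backgroundLevel,
      speckleMean = speckleMean, speckleSD = speckleSD,
      valveCenter = as.numeric(valveCenter),
      valveOuterRadius = valveOuterRadius,
      valveInnerRadius = valveInnerRadius, valveLevel = valveLevel,
      calciumBlobs = calciumBlobs, seed = as.integer(seed))
}

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(paste0("SceneParams %dx%d px, apex (%.0f, %.0f), ",
                     "half-angle %.0f deg, %d calcium blob(s), seed %d\n"),
              object@imageSize, object@imageSize,
              object@coneApex[1L], object@coneApex[2L],
              object@coneHalfAngle, nrow(object@calciumBlobs), object@seed))
})

## Vectorized point-in-sector test (x, y at pixel-center coordinates).
.insideSector <- function(x, y, apex, halfAngleDeg, radius) {
  dx <- x - apex[1L]; dy <- y - apex[2L]
  r <- sqrt(dx^2 + dy^2)
  ang <- acos(pmin(1, pmax(-1, ifelse(r > 0, dy / r, 1))))
  r <= radius & ang <= halfAngleDeg * pi / 180
}

## Check that a circle lies fully inside the scene's sector.
.circleInsideSector <- function(center, radius, params, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  all(.insideSector(center[1L] + radius * cos(th),
                    center[2L] + radius * sin(th),
                    params@coneApex, params@coneHalfAngle,
                    params@coneRadius))
}

## Pixel-center coordinate grids for an S x S image (0-based + 0.5).
.pixelGrid <- function(S) {
  cx <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)
  cy <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)
  list(x = cx, y = cy)
}

#' Rasterize the analytic sector mask of a scene
#'
#' The exact cone interior of a `SceneParams`, used as ground truth when
#' evaluating [detectCone()].
#'
#' @param params A `SceneParams`.
#' @return A logical `imageSize` x `imageSize` matrix.
#' @export
sectorMask <- function(params) {
  g <- .pixelGrid(params@imageSize)
  m <- .insideSector(g$x, g$y, params@coneApex, params@coneHalfAngle,
                     params@coneRadius)
  dim(m) <- c(params@imageSize, params@imageSize)
  m
}

#' Generate one synthetic echocardiogram scene
#'
#' Renders the scene described by `params` and returns it together with
#' exact ground truth.  The valve box is the tight axis-aligned box of the
#' painted ring pixels; `calcified` is TRUE iff at least one calcium blob
#' with positive intensity is present.  Rendering is fully seeded: the same
#' parameters give a bit-identical image.
#'
#' @param params A `SceneParams`; the valve ring and every calcium blob must
#'   lie entirely inside the cone (a `GeometryError` is signalled otherwise).
#' @param blobThreshold Gray level used for the `blobPixels` ground-truth
#'   count (pixels strictly brighter than this; default 220).
#' @return A list with `image` (H x W x 3 array, three identical channels)
#'   and `truth`, a list with `valveBox` (`BoundingBox`), `calcified`
#'   (logical) and `blobPixels` (count).
#' @examples
#' sc <- generateScene(SceneParams(imageSize = 256, speckleSD = 0))
#' sc$truth$valveBox
#' @export
generateScene <- function(params, blobThreshold = 220) {
  validObject(params)
  .assert(.circleInsideSector(params@valveCenter, params@valveOuterRadius,
                              params),
          "GeometryError", "valve ring crosses the cone boundary")
  blobs <- params@calciumBlobs
  if (nrow(blobs)) {
    for (i in seq_len(nrow(blobs)))
      .assert(.circleInsideSector(c(blobs$x[i], blobs$y[i]),
                                  blobs$radius[i], params),
              "GeometryError", "calcium blob %d crosses the cone boundary", i)
  }

  S <- params@imageSize
  g <- .pixelGrid(S)
  inside <- .insideSector(g$x, g$y, params@coneApex, params@coneHalfAngle,
                          params@coneRadius)

  set.seed(params@seed)
  img <- matrix(params@backgroundLevel, S, S)
  n <- sum(inside)
  img[inside] <- pmin(255, pmax(0, round(
    rnorm(n, params@speckleMean, params@speckleSD))))

  ## valve ring: painted at exactly valveLevel
  dv <- sqrt((g$x - params@valveCenter[1L])^2 +
             (g$y - params@valveCenter[2L])^2)
  ring <- dv <= params@valveOuterRadius & dv >= params@valveInnerRadius
  img[ring] <- params@valveLevel

  ## calcium blobs: Gaussian-profiled discs, peak exactly at intensity;
  ## centers snap to the nearest pixel center so the stated peak is attained
  if (nrow(blobs)) {
    for (i in seq_len(nrow(blobs))) {
      bc <- floor(c(blobs$x[i], blobs$y[i])) + 0.5
      sigma <- blobs$radius[i] / 2
      d2 <- (g$x - bc[1L])^2 + (g$y - bc[2L])^2
      sel <- d2 <= (2 * blobs$radius[i])^2
      prof <- round(blobs$intensity[i] * exp(-d2[sel] / (2 * sigma^2)))
      img[sel] <- pmax(img[sel], prof)
    }
  }

  ringIdx <- which(ring, arr.ind = TRUE)
  valveBox <- BoundingBox(min(ringIdx[, 2L]) - 1L, min(ringIdx[, 1L]) - 1L,
                          max(ringIdx[, 2L]), max(ringIdx[, 1L]))
  truth <- list(valveBox = valveBox,
                calcified = nrow(blobs) > 0 && any(blobs$intensity > 0),
                blobPixels = sum(img > blobThreshold))
  list(image = .asRGB(img), truth = truth)
}

## Draw jittered per-sample scene parameters around base_params.
.jitterParams <- function(base, calcified, sceneSeed) {
  S <- base@imageSize
  repeat {
    ctr <- base@valveCenter + runif(2L, -0.1, 0.1) * S
    outer <- base@valveOuterRadius * runif(1L, 0.8, 1.2)
    inner <- outer * base@valveInnerRadius / base@valveOuterRadius
    blobs <- data.frame()
    if (calcified) {
      nb <- sample(1:3, 1L)
      th <- runif(nb, 0, 2 * pi)
      rmid <- (inner + outer) / 2
      blobs <- data.frame(x = ctr[1L] + rmid * cos(th),
                          y = ctr[2L] + rmid * sin(th),
                          radius = pmax(2, runif(nb, 0.008, 0.016) * S),
                          intensity = 255)
    }
    p <- SceneParams(imageSize = S, coneApex = base@coneApex,
                     coneHalfAngle = base@coneHalfAngle,
                     coneRadius = base@coneRadius,
                     backgroundLevel = base@backgroundLevel,
                     speckleMean = base@speckleMean,
                     speckleSD = base@speckleSD,
                     valveCenter = ctr, valveOuterRadius = outer,
                     valveInnerRadius = inner, valveLevel = base@valveLevel,
                     calciumBlobs = blobs, seed = sceneSeed)
    okBlobs <- !nrow(blobs) ||
      all(vapply(seq_len(nrow(blobs)), function(i)
        .circleInsideSector(c(blobs$x[i], blobs$y[i]), blobs$radius[i], p),
        logical(1L)))
    if (.circleInsideSector(ctr, outer, p) && okBlobs) return(p)
  }
}

#' Generate a labeled synthetic dataset
#'
#' Writes `nCalcified + nHealthy` synthetic scenes to `dir` as
#' `STUDY_<nnn>.png` (anonymized-style sequential naming) with per-sample
#' jitter of the valve position (uniform within +/-10 percent of the image
#' size) and ring size (+/-20 percent), plus the annotation CSV
#' (`annotations.csv`) and a ground-truth sidecar
#' (`ground_truth.csv`: image_id, calcified, blob_pixels, patient_id).
#' Calcified samples receive 1-3 peak-255 calcium blobs on the ring.
#'
#' @param nCalcified,nHealthy Number of calcified / healthy samples.
#' @param baseParams A `SceneParams` giving the shared scene geometry;
#'   per-sample parameters are jittered around it.
#' @param seed Integer seed driving the jitter and the per-scene seeds.
#' @param dir Output directory (created if needed).
#' @return An `EchoManifest` with one row per sample.
#' @examples
#' \donttest{
#' m <- generateDataset(2, 3, SceneParams(imageSize = 256), seed = 1,
#'                      dir = tempfile())
#' nSamples(m)
#' }
#' @export
generateDataset <- function(nCalcified, nHealthy,
                            baseParams = SceneParams(), seed = 0,
                            dir = tempfile("echoset")) {
  .assert(nCalcified >= 0 && nHealthy >= 0, "ValueError",
          "sample counts must be >= 0")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nCalcified + nHealthy
  set.seed(seed)
  labels <- sample(rep(c(TRUE, FALSE), c(nCalcified, nHealthy)))
  sceneSeeds <- sample.int(.Machine$integer.max - 1L, n)

  recs <- vector("list", n)
  truthRows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("STUDY_%03d", i - 1L)
    p <- .jitterParams(baseParams, labels[i], sceneSeeds[i])
    sc <- generateScene(p)
    path <- file.path(dir, paste0(id, ".png"))
    writeEchoImage(sc$image, path)
    b <- sc$truth$valveBox
    recs[[i]] <- data.frame(image_id = id, path = path,
                            calcified = labels[i],
                            x_min = b@xmin, y_min = b@ymin,
                            x_max = b@xmax, y_max = b@ymax,
                            width = p@imageSize, height = p@imageSize,
                            stringsAsFactors = FALSE)
    truthRows[[i]] <- data.frame(image_id = id, calcified = labels[i],
                                 blob_pixels = sc$truth$blobPixels,
                                 patient_id = id, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  manifest <- EchoManifest(records)
  writeAnnotationsCsv(records, file.path(dir, "annotations.csv"))
  write.csv(do.call(rbind, truthRows), file.path(dir, "ground_truth.csv"),
            row.names = FALSE, quote = FALSE)
  manifest
}
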