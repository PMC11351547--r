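#' Valve detector configuration
#'
#' Training configuration of the aortic valve detector: 640 x 640 inputs,
#' batch size 32, 75 epochs and an 80/10/10 train/validation/test split by
#' default.  The backbone id selects the window descriptor the detector
#' scores (`"window-s"`: 12 x 12 normalized intensity patches with a
#' 16-unit scoring head; `"window-l"`: 16 x 16 patches, 32 units).
#'
#' @slot inputSize Square input side in pixels (default 640).
#' @slot batchSize Nominal batch size (default 32; training is full-batch
#'   deterministic, the value is recorded for provenance).
#' @slot epochs Training epochs (default 75).
#' @slot split Train/validation/test fractions summing to 1.
#' @slot backboneId Window descriptor id.
#' @slot confidenceThreshold Minimum confidence for a reported detection
#'   (default 0.25).
#' @slot seed Integer seed for sampling and initialization.
#' @param inputSize,batchSize,epochs,split,backboneId See slots.
#' @param confidenceThreshold,seed See slots.
#' @aliases DetectorConfig-class
#' @exportClass DetectorConfig
setClass("DetectorConfig", representation(
  inputSize = "integer", batchSize = "integer", epochs = "integer",
  split = "numeric", backboneId = "character",
  confidenceThreshold = "numeric", seed = "integer"))

setValidity("DetectorConfig", function(object) {
  if (abs(sum(object@split) - 1) > 1e-8) return("split must sum to 1")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (!object@backboneId %in% names(.detectorBackbones))
    return(paste("unknown backboneId; use one of:",
                 paste(names(.detectorBackbones), collapse = ", ")))
  TRUE
})

#' @rdname DetectorConfig-class
#' @export
DetectorConfig <- function(inputSize = 640, batchSize = 32, epochs = 75,
                           split = c(0.8, 0.1, 0.1),
                           backboneId = "window-s",
                           confidenceThreshold = 0.25, seed = 0) {
  new("DetectorConfig", inputSize = as.integer(inputSize),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      split = split, backboneId = backboneId,
      confidenceThreshold = confidenceThreshold, seed = as.integer(seed))
}

.detectorBackbones <- list(
  `window-s` = list(grid = 12L, hidden = 16L),
  `window-l` = list(grid = 16L, hidden = 32L))

#' One detection
#'
#' @slot box The detected `BoundingBox`.
#' @slot confidence Detection confidence in `[0, 1]`.
#' @aliases DetectionResult-class
#' @exportClass DetectionResult
setClass("DetectionResult",
         representation(box = "BoundingBox", confidence = "numeric"))

setValidity("DetectionResult", function(object) {
  if (object@confidence < 0 || object@confidence > 1)
    return("confidence must be in [0, 1]")
  TRUE
})

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult conf %.3f: ", object@confidence))
  show(object@box)
})

#' @rdname DetectionResult-class
#' @param object A `DetectionResult`.
#' @export
detectionBox <- function(object) object@box

#' @rdname DetectionResult-class
#' @export
detectionConfidence <- function(object) object@confidence

#' Trained valve detector
#'
#' Handle returned by [trainDetector()]: a sliding-window detector that
#' scores multi-scale square windows of a downscaled working image with a
#' small dense head over normalized intensity-patch descriptors.
#'
#' @slot net Fitted scoring head (weights, feature standardization).
#' @slot scales Window sides, in working-image pixels.
#' @slot workSize Longest side of the working image the windows live on.
#' @slot grid Descriptor patch resolution (grid x grid samples per window).
#' @slot config The [DetectorConfig-class] used for training.
#' @slot lossLog data.frame of (epoch, loss) from training.
#' @slot valMetrics Validation-set detection metrics (empty list when no
#'   validation manifest was supplied).
#' @aliases EchoDetector-class
#' @exportClass EchoDetector
setClass("EchoDetector", representation(
  net = "list", scales = "numeric", workSize = "integer", grid = "integer",
  config = "DetectorConfig", lossLog = "data.frame", valMetrics = "list"))

setMethod("show", "EchoDetector", function(object) {
  cat(sprintf(paste0("EchoDetector (%s): %d-epoch fit, final loss %.4f, ",
                     "window scales %s @ work size %d\n"),
              object@config@backboneId, nrow(object@lossLog),
              tail(object@lossLog$loss, 1L),
              paste(round(object@scales), collapse = "/"),
              object@workSize))
})

#' @rdname EchoDetector-class
#' @param object An `EchoDetector`.
#' @export
trainingLossLog <- function(object) object@lossLog

## Downscale a grayscale image so its longest side is workSize.
.toWorkImage <- function(gray, workSize) {
  f <- workSize / max(dim(gray))
  if (abs(f - 1) < 1e-9) return(list(image = gray, factor = 1))
  out <- EBImage::resize(t(gray), w = round(nrow(gray) * f),
                         h = round(ncol(gray) * f))
  list(image = t(out), factor = f)
}

## Candidate windows (square, fully inside) for one work image.
.candidateWindows <- function(h, w, scales) {
  out <- list()
  for (s in scales) {
    s <- round(s)
    if (s > min(h, w)) next
    stride <- max(2L, round(s / 6))
    xs <- unique(c(seq(0L, w - s, by = stride), w - s))
    ys <- unique(c(seq(0L, h - s, by = stride), h - s))
    out[[length(out) + 1L]] <- cbind(x = rep(xs, times = length(ys)),
                                     y = rep(ys, each = length(xs)),
                                     s = s)
  }
  do.call(rbind, out)
}

## Normalized grid x grid intensity descriptors for a set of windows
## (rows of win: x, y, s in work-image coordinates).
.windowFeatures <- function(workImg, win, grid) {
  nwin <- nrow(win)
  rel <- (seq_len(grid) - 0.5) / grid
  ## sample coordinates: for window i, cell j -> x_i + rel_j * s_i
  gx <- outer(rel, win[, "s"])  # grid x nwin
  gy <- gx
  X <- matrix(0, nwin, grid * grid)
  xs <- rep(seq_len(grid), times = grid)
  ys <- rep(seq_len(grid), each = grid)
  for (j in seq_len(grid * grid)) {
    X[, j] <- .bilinearSample(workImg,
                              win[, "x"] + gx[xs[j], ],
                              win[, "y"] + gy[ys[j], ])
  }
  mu <- rowMeans(X)
  sdv <- pmax(sqrt(rowMeans(X^2) - mu^2), 1e-6)
  (X - mu) / sdv
}

.windowBox <- function(x, y, s, factor) {
  BoundingBox(x / factor, y / factor, (x + s) / factor, (y + s) / factor)
}

## Vectorized IoU of square windows (rows x, y, s) against one box given as
## a numeric c(xmin, ymin, xmax, ymax) in the same coordinates.
.windowIoUs <- function(win, b) {
  ix <- pmax(0, pmin(win[, "x"] + win[, "s"], b[3L]) -
                pmax(win[, "x"], b[1L]))
  iy <- pmax(0, pmin(win[, "y"] + win[, "s"], b[4L]) -
                pmax(win[, "y"], b[2L]))
  inter <- ix * iy
  inter / (win[, "s"]^2 + (b[3L] - b[1L]) * (b[4L] - b[2L]) - inter)
}

#' Train the aortic valve detector
#'
#' Trains a sliding-window valve detector: every training frame is
#' downscaled to a working resolution, multi-scale square windows are
#' labeled positive (IoU with the annotated valve box >= 0.5) or negative
#' (IoU <= 0.25, preferring hard negatives that brush the valve), and a
#' small dense scoring head (rectified hidden layer, sigmoid output) is
#' fitted on normalized intensity-patch descriptors by seeded full-batch
#' gradient descent.
#' Window scales are derived from the training boxes themselves.  Training
#' is deterministic for a given manifest, configuration and seed.
#'
#' @param trainManifest,valManifest `EchoManifest`s with valve boxes
#'   (`valManifest` may be NULL; it is only used for the logged validation
#'   metrics).
#' @param config A [DetectorConfig-class].
#' @param workSize Working-image longest side in pixels (default 160).
#' @param negPerImage Negative windows sampled per training image.
#' @param runDir Optional directory; when given, the loss log is written to
#'   `loss.csv` there.
#' @return An [EchoDetector-class].
#' @export
trainDetector <- function(trainManifest, valManifest = NULL, config =
                            DetectorConfig(), workSize = 160,
                          negPerImage = 40L, runDir = NULL) {
  .assert(nSamples(trainManifest) > 0L, "DataError",
          "training manifest is empty")
  r <- manifestRecords(trainManifest)
  .assert(!anyNA(r$x_min), "DataError",
          "all training records need valve boxes")
  grid <- .detectorBackbones[[config@backboneId]]$grid
  workSize <- as.integer(workSize)

  ## window scales from the annotated box sizes (median side, +/-25%)
  sides <- pmax(r$x_max - r$x_min, r$y_max - r$y_min) *
    workSize / pmax(r$width, r$height)
  s0 <- stats::median(sides)
  scales <- s0 * c(0.8, 1, 1.25)

  set.seed(config@seed)
  feats <- list(); labs <- list()
  for (i in seq_len(nrow(r))) {
    smp <- loadSample(trainManifest, i)
    wk <- .toWorkImage(.asGray(smp$image), workSize)
    win <- .candidateWindows(nrow(wk$image), ncol(wk$image), scales)
    truth <- smp$box
    ious <- .windowIoUs(win, .boxToVec(truth) * wk$factor)
    ## positives only from tightly aligned windows; the (0.25, 0.65) band is
    ## ignored entirely, otherwise marginally overlapping windows get full
    ## positive credit and the score plateaus instead of peaking on the
    ## best-centered window
    pos <- which(ious >= 0.65)
    if (!length(pos)) pos <- which.max(ious)
    ## negatives: prefer hard ones (windows brushing the valve) so the
    ## scorer learns to reject partial-ring views, then far background
    hard <- which(ious > 0 & ious <= 0.25)
    far <- which(ious == 0)
    nHard <- min(length(hard), ceiling(negPerImage / 2))
    hard <- hard[sort(sample.int(length(hard), nHard))]
    far <- far[sort(sample.int(length(far),
                               min(length(far), negPerImage - nHard)))]
    neg <- c(hard, far)
    sel <- c(pos, neg)
    feats[[i]] <- .windowFeatures(wk$image, win[sel, , drop = FALSE], grid)
    labs[[i]] <- rep(c(1, 0), c(length(pos), length(neg)))
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  hidden <- .detectorBackbones[[config@backboneId]]$hidden
  net <- .fitDenseNet(X, y, hidden = hidden, epochs = config@epochs,
                      lr = 0.2, seed = config@seed)
  model <- new("EchoDetector", net = net, scales = scales,
               workSize = workSize, grid = as.integer(grid),
               config = config, lossLog = net$lossLog, valMetrics = list())
  if (!is.null(valManifest) && nSamples(valManifest) > 0L)
    model@valMetrics <- metricsAsList(evaluateDetector(model, valManifest))
  if (!is.null(runDir)) {
    dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(net$lossLog, file.path(runDir, "loss.csv"), row.names = FALSE)
  }
  model
}

#' Evaluate a detector on an annotated manifest
#'
#' Runs [detectValve()] on every record, keeps the best detection per frame,
#' and matches it against the annotated box at the given IoU threshold.
#'
#' @param model An [EchoDetector-class].
#' @param manifest An `EchoManifest` with valve boxes.
#' @param iouThreshold Matching threshold (default 0.5).
#' @return A [MetricsReport-class].
#' @export
evaluateDetector <- function(model, manifest, iouThreshold = 0.5) {
  r <- manifestRecords(manifest)
  preds <- list(); truths <- list()
  for (i in seq_len(nrow(r))) {
    smp <- loadSample(manifest, i)
    best <- selectBest(detectValve(model, smp$image))
    preds[[r$image_id[i]]] <- if (is.null(best)) list() else list(best)
    truths[[r$image_id[i]]] <- smp$box
  }
  matchDetections(preds, truths, iouThreshold = iouThreshold)
}

## Greedy non-maximum suppression on rows of (score, box list).
.nms <- function(boxes, scores, overlap = 0.45) {
  keep <- integer(0)
  ord <- order(-scores, seq_along(scores))  # stable: first wins ties
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    ord <- ord[-1L]
    if (!length(ord)) break
    ious <- vapply(ord, function(j) iou(boxes[[i]], boxes[[j]]), numeric(1L))
    ord <- ord[ious <= overlap]
  }
  keep
}

#' Detect the aortic valve in a frame
#'
#' Scores all multi-scale candidate windows of the frame with the trained
#' detector, suppresses overlapping candidates, refines the survivors by a
#' local position/scale search, and returns detections above the
#' configuration's confidence threshold, sorted by decreasing confidence.
#'
#' @param model An [EchoDetector-class].
#' @param image 8-bit image array.
#' @param confidenceThreshold Override of the config threshold.
#' @return A list of [DetectionResult-class] objects (possibly empty),
#'   sorted by decreasing confidence.
#' @export
detectValve <- function(model, image,
                        confidenceThreshold =
                          model@config@confidenceThreshold) {
  gray <- .asGray(image)
  if (!any(gray > 0)) return(list())
  wk <- .toWorkImage(gray, model@workSize)
  win <- .candidateWindows(nrow(wk$image), ncol(wk$image), model@scales)
  if (is.null(win) || !nrow(win)) return(list())
  X <- .windowFeatures(wk$image, win, model@grid)
  z <- .predictDenseNet(model@net, X, logits = TRUE)
  p <- .sigmoid(z)
  cand <- which(p >= confidenceThreshold)
  if (!length(cand)) return(list())
  boxes <- lapply(cand, function(k)
    .windowBox(win[k, 1L], win[k, 2L], win[k, 3L], wk$factor))
  ## rank by logit: probabilities saturate at 1 for every strong candidate
  keep <- .nms(boxes, z[cand])
  keep <- keep[seq_len(min(3L, length(keep)))]

  ## local refinement of each kept window in work coordinates; the argmax
  ## runs over logits so refinement still discriminates when the sigmoid
  ## saturates
  refined <- lapply(keep, function(k0) {
    k <- cand[k0]
    x0 <- win[k, 1L]; y0 <- win[k, 2L]; s0 <- win[k, 3L]
    step <- max(1, round(s0 / 12))
    offs <- c(-step, 0, step)
    grid3 <- expand.grid(dx = offs, dy = offs, f = c(0.9, 1, 1.1))
    wref <- cbind(x = x0 + grid3$dx, y = y0 + grid3$dy,
                  s = round(s0 * grid3$f))
    ok <- wref[, "x"] >= 0 & wref[, "y"] >= 0 &
      wref[, "x"] + wref[, "s"] <= ncol(wk$image) &
      wref[, "y"] + wref[, "s"] <= nrow(wk$image)
    wref <- wref[ok, , drop = FALSE]
    zr <- .predictDenseNet(model@net, .windowFeatures(wk$image, wref,
                                                      model@grid),
                           logits = TRUE)
    b <- which.max(zr)
    list(logit = zr[b],
         det = new("DetectionResult",
                   box = .windowBox(wref[b, 1L], wref[b, 2L], wref[b, 3L],
                                    wk$factor),
                   confidence = as.numeric(.sigmoid(zr[b]))))
  })
  zBest <- vapply(refined, `[[`, numeric(1L), "logit")
  lapply(refined[order(-zBest, seq_along(zBest))], `[[`, "det")
}

#' Keep the single best detection
#'
#' The imaged view contains one aortic valve, so only the highest-confidence
#' detection is kept; ties resolve to the earlier result (stable sort).
#'
#' @param results A list of [DetectionResult-class] objects.
#' @return The best `DetectionResult`, or NULL for an empty list.
#' @export
selectBest <- function(results) {
  if (!length(results)) return(NULL)
  conf <- vapply(results, detectionConfidence, numeric(1L))
  results[[order(-conf, seq_along(conf))[1L]]]
}
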