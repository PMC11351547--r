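#' Calcification classifier configuration
#'
#' Training configuration of the valve-region calcification classifier:
#' 224 x 224 inputs, batch size 1, 50 epochs and an 80/20 train/test split
#' by default, a feature-extraction backbone with a selectable pooling mode,
#' and a 120-unit dense head.
#'
#' Backbones are fixed descriptor banks computed on a grid over the resized
#' valve region; `pooling` controls how the grid map reaches the dense head:
#' `"none"` flattens the full grid x grid x channels map, `"max"` and
#' `"avg"` pool each channel over the grid, leaving one value per channel.
#'
#' @slot inputSize Square input side in pixels (default 224).
#' @slot batchSize Nominal batch size (default 1; training is full-batch
#'   deterministic, the value is recorded for provenance).
#' @slot epochs Training epochs (default 50).
#' @slot split Train/test fractions summing to 1 (default 0.8/0.2).
#' @slot backboneId One of `pool-4`, `pool-8`, `pool-16` (intensity
#'   statistics) or `grad-4`, `grad-8`, `grad-16` (intensity plus gradient
#'   statistics), the number giving the grid resolution.
#' @slot pooling One of `"none"`, `"max"`, `"avg"`.
#' @slot headWidth Dense-layer width (default 120).
#' @slot cutoff Decision cutoff on the calcification probability, applied
#'   with the `>=` convention (default 0.5).
#' @slot seed Integer seed.
#' @param inputSize,batchSize,epochs,split,backboneId See slots.
#' @param pooling,headWidth,cutoff,seed See slots.
#' @aliases ClassifierConfig-class
#' @exportClass ClassifierConfig
setClass("ClassifierConfig", representation(
  inputSize = "integer", batchSize = "integer", epochs = "integer",
  split = "numeric", backboneId = "character", pooling = "character",
  headWidth = "integer", cutoff = "numeric", seed = "integer"))

## Descriptor banks: intensity statistics (and, for the grad-* family,
## gradient statistics) on a G x G grid over the resized region.
.classifierBackbones <- list(
  `pool-4`  = list(grid = 4L, gradient = FALSE),
  `pool-8`  = list(grid = 8L, gradient = FALSE),
  `pool-16` = list(grid = 16L, gradient = FALSE),
  `grad-4`  = list(grid = 4L, gradient = TRUE),
  `grad-8`  = list(grid = 8L, gradient = TRUE),
  `grad-16` = list(grid = 16L, gradient = TRUE))

setValidity("ClassifierConfig", function(object) {
  if (!object@pooling %in% c("none", "max", "avg"))
    return("pooling must be one of none, max, avg")
  if (!object@backboneId %in% names(.classifierBackbones))
    return(paste("unknown backboneId; use one of:",
                 paste(names(.classifierBackbones), collapse = ", ")))
  if (abs(sum(object@split) - 1) > 1e-8) return("split must sum to 1")
  if (object@headWidth < 1L) return("headWidth must be >= 1")
  TRUE
})

#' @rdname ClassifierConfig-class
#' @export
ClassifierConfig <- function(inputSize = 224, batchSize = 1, epochs = 50,
                             split = c(0.8, 0.2), backboneId = "pool-8",
                             pooling = "none", headWidth = 120,
                             cutoff = 0.5, seed = 0) {
  new("ClassifierConfig", inputSize = as.integer(inputSize),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      split = split, backboneId = backboneId, pooling = pooling,
      headWidth = as.integer(headWidth), cutoff = cutoff,
      seed = as.integer(seed))
}

#' Calcification classifier model handle
#'
#' Built by [buildClassifier()] (untrained head, seeded initialization) and
#' fitted by [trainClassifier()].
#'
#' @slot net Dense head (weights, feature standardization); untrained heads
#'   hold seeded random weights, so their outputs are already valid
#'   probabilities in (0, 1).
#' @slot config The [ClassifierConfig-class].
#' @slot lossLog data.frame of (epoch, loss); empty until trained.
#' @aliases EchoClassifier-class
#' @exportClass EchoClassifier
setClass("EchoClassifier", representation(
  net = "list", config = "ClassifierConfig", lossLog = "data.frame"))

setMethod("show", "EchoClassifier", function(object) {
  state <- if (nrow(object@lossLog))
    sprintf("trained %d epochs, final loss %.4f", nrow(object@lossLog),
            tail(object@lossLog$loss, 1L)) else "untrained"
  cat(sprintf("EchoClassifier (%s, pooling %s, dense %d): %s\n",
              object@config@backboneId, object@config@pooling,
              object@config@headWidth, state))
})

## Resize a grayscale matrix to size x size (bilinear).
.resizeGray <- function(gray, size) {
  if (all(dim(gray) == size)) return(gray)
  t(EBImage::resize(t(gray), w = size, h = size))
}

## G x G x C descriptor map of a resized region (values scaled to [0, 1]).
.descriptorMap <- function(gray, backbone, inputSize) {
  g <- .resizeGray(gray, inputSize) / 255
  G <- backbone$grid
  cell <- inputSize %/% G
  stopifnot(cell * G == inputSize)
  chans <- list(
    mean = g, bright75 = (g > 0.75) * 1, bright90 = (g > 0.9) * 1)
  if (backbone$gradient) {
    dx <- cbind(g[, -1L] - g[, -ncol(g)], 0)
    dy <- rbind(g[-1L, ] - g[-nrow(g), ], 0)
    chans$gradx <- abs(dx); chans$grady <- abs(dy)
  }
  blockStat <- function(m, stat) {
    out <- matrix(0, G, G)
    for (i in seq_len(G)) for (j in seq_len(G)) {
      blk <- m[((i - 1L) * cell + 1L):(i * cell),
               ((j - 1L) * cell + 1L):(j * cell)]
      out[i, j] <- if (stat == "mean") mean(blk)
                   else if (stat == "max") max(blk) else stats::sd(blk)
    }
    out
  }
  maps <- list(blockStat(chans$mean, "mean"),
               blockStat(chans$mean, "max"),
               blockStat(chans$mean, "sd"),
               blockStat(chans$bright75, "mean"),
               blockStat(chans$bright90, "mean"))
  if (backbone$gradient)
    maps <- c(maps, list(blockStat(chans$gradx, "mean"),
                         blockStat(chans$grady, "mean")))
  array(unlist(maps), dim = c(G, G, length(maps)))
}

## Feature vector for one valve region under a config.
.classifierFeatures <- function(gray, config) {
  bb <- .classifierBackbones[[config@backboneId]]
  fmap <- .descriptorMap(gray, bb, config@inputSize)
  switch(config@pooling,
         none = as.vector(fmap),
         max = apply(fmap, 3L, max),
         avg = apply(fmap, 3L, mean))
}

#' Build an (untrained) calcification classifier
#'
#' Assembles the model: descriptor-bank feature extraction with the
#' configured pooling mode, a rectified dense layer of `headWidth` units and
#' a sigmoid output.  The head weights are seeded random values, so the
#' untrained model already maps any region to a probability in (0, 1).
#'
#' @param config A [ClassifierConfig-class].
#' @return An [EchoClassifier-class].  Signals a `ConfigError` for an
#'   unknown backbone or pooling mode.
#' @export
buildClassifier <- function(config = ClassifierConfig()) {
  v <- validObject(config, test = TRUE)
  if (!isTRUE(v)) .stopWith("ConfigError", "%s", v)
  bb <- .classifierBackbones[[config@backboneId]]
  nchan <- if (bb$gradient) 7L else 5L
  d <- if (config@pooling == "none") bb$grid^2 * nchan else nchan
  set.seed(config@seed)
  net <- list(
    W1 = matrix(rnorm(d * config@headWidth, sd = 1 / sqrt(d)),
                d, config@headWidth),
    b1 = rep(0, config@headWidth),
    W2 = matrix(rnorm(config@headWidth, sd = 1 / sqrt(config@headWidth)),
                config@headWidth, 1L),
    b2 = 0, hidden = config@headWidth, mu = rep(0, d), sd = rep(1, d))
  new("EchoClassifier", net = net, config = config,
      lossLog = data.frame(epoch = integer(), loss = numeric()))
}

#' @rdname buildClassifier
#' @param model An `EchoClassifier`.
#' @details `classifierFeatureLength(model)` gives the backbone feature
#'   dimension seen by the dense head (grid^2 x channels for pooling
#'   `"none"`, channels otherwise).
#' @export
classifierFeatureLength <- function(model) {
  nrow(model@net$W1)
}

## Valve region of one manifest record, denoised, as grayscale.
.loadRoiGray <- function(manifest, i, denoise = TRUE) {
  smp <- loadSample(manifest, i)
  img <- smp$image
  if (!is.null(smp$box)) img <- cropRoi(img, smp$box)
  g <- .asGray(img)
  if (denoise) g <- reduceNoise(g)
  g
}

#' Train the calcification classifier
#'
#' Extracts backbone features from every training record's valve region
#' (cropped at its box, noise-reduced, resized to the configured input
#' size) and fits the dense head by seeded full-batch gradient descent with
#' binary cross-entropy loss.  A training set with only one class present
#' yields a warning (such a fit can only ever predict that class).
#'
#' @param trainManifest An `EchoManifest` of labeled valve samples.
#' @param config A [ClassifierConfig-class].
#' @param denoise Apply [reduceNoise()] to each region (default TRUE).
#' @param runDir Optional directory for the `loss.csv` training log.
#' @return A trained [EchoClassifier-class].
#' @export
trainClassifier <- function(trainManifest, config = ClassifierConfig(),
                            denoise = TRUE, runDir = NULL) {
  .assert(nSamples(trainManifest) > 0L, "DataError",
          "training manifest is empty")
  r <- manifestRecords(trainManifest)
  if (length(unique(r$calcified)) < 2L)
    warning("training split contains a single class; the fitted model ",
            "will always predict it", call. = FALSE)
  model <- buildClassifier(config)
  X <- t(vapply(seq_len(nrow(r)), function(i)
    .classifierFeatures(.loadRoiGray(trainManifest, i, denoise), config),
    numeric(classifierFeatureLength(model))))
  net <- .fitDenseNet(X, r$calcified, hidden = config@headWidth,
                      epochs = config@epochs, lr = 0.2, seed = config@seed)
  if (!is.null(runDir)) {
    dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(net$lossLog, file.path(runDir, "loss.csv"), row.names = FALSE)
  }
  new("EchoClassifier", net = net, config = config, lossLog = net$lossLog)
}

#' Classify a valve region
#'
#' Applies the classifier to one valve region image and thresholds the
#' probability at the configured cutoff (`>=` convention).
#'
#' @param model A (trained) [EchoClassifier-class].
#' @param roiImage The valve region (any size; it is resized to the model's
#'   input size), grayscale matrix or RGB array.
#' @param denoise Apply [reduceNoise()] first (default TRUE, matching
#'   training).
#' @return A [ClassificationResult-class].
#' @export
classifyRoi <- function(model, roiImage, denoise = TRUE) {
  g <- .asGray(roiImage)
  if (denoise) g <- reduceNoise(g)
  x <- .classifierFeatures(g, model@config)
  p <- .predictDenseNet(model@net, matrix(x, 1L))
  ClassificationResult(as.numeric(p), cutoff = model@config@cutoff)
}
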