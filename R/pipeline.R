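#' Run the full screening pipeline on one frame
#'
#' The end-to-end chain: (optionally) extract and standardize the ultrasound
#' sector, locate the aortic valve with the detector, keep the best
#' detection, crop the valve region and classify it — with the trained
#' classifier when one is given, otherwise with the white-pixel heuristic at
#' `threshold` (a path with no trained-weight dependency at all).  When
#' nothing is detected the frame's calcification status is reported as
#' undetermined (`NA`) rather than guessed.
#'
#' @param image 8-bit image array (or a PNG path).
#' @param detector A trained [EchoDetector-class].
#' @param classifier Optional trained [EchoClassifier-class]; when NULL the
#'   heuristic classifier is used.
#' @param threshold Binarization threshold for the heuristic path
#'   (default 220).
#' @param preprocess Run sector extraction and standardization first
#'   (default TRUE; set FALSE for frames already standardized or synthetic
#'   scenes used as-is).
#' @param size Standardization window (default 640), only with
#'   `preprocess = TRUE`.
#' @return A list with `valve_box` (`BoundingBox` or NULL), `confidence`,
#'   `calcified` (logical or NA) and `probability`.  Box coordinates refer
#'   to the frame the detector saw (the standardized frame when
#'   `preprocess = TRUE`; its origin in the source is returned as `offset`).
#' @export
runPipeline <- function(image, detector, classifier = NULL, threshold = 220,
                        preprocess = TRUE, size = 640) {
  if (is.character(image)) image <- readEchoImage(image)
  offset <- c(x = 0L, y = 0L)
  if (preprocess) {
    cone <- tryCatch(detectCone(image), error = function(e) {
      if (inherits(e, "DetectionError")) NULL else stop(e)
    })
    if (is.null(cone)) {
      return(list(valve_box = NULL, confidence = NA_real_,
                  calcified = NA, probability = NA_real_,
                  offset = offset, note = "preprocess: no foreground"))
    }
    cropped <- maskAndTightCrop(image, cone)
    std <- standardizeCrop(cropped$image, size = size)
    offset <- cropped$offset + std$offset
    image <- std$image
  }
  dets <- detectValve(detector, image)
  best <- selectBest(dets)
  if (is.null(best)) {
    return(list(valve_box = NULL, confidence = NA_real_, calcified = NA,
                probability = NA_real_, offset = offset,
                note = "detector: no valve found"))
  }
  box <- .clipBox(detectionBox(best), .imageDim(image)["w"],
                  .imageDim(image)["h"])
  roi <- cropRoi(image, box)
  res <- if (is.null(classifier)) heuristicClassify(roi, threshold)
         else classifyRoi(classifier, roi)
  list(valve_box = box, confidence = detectionConfidence(best),
       calcified = isCalcified(res), probability = calcifiedProbability(res),
       offset = offset)
}

.runConfigKeys <- c("seed", "out_dir", "log_level", "heuristic_threshold",
                    "techniques", "split_mode", "scene", "detector",
                    "classifier", "paths")

#' Read or write a pipeline run configuration
#'
#' Run configurations are plain YAML with a fixed key set (`seed`,
#' `out_dir`, `log_level`, `heuristic_threshold`, `techniques`,
#' `split_mode`, `scene`, `detector`, `classifier`, `paths`); unknown keys
#' are rejected so typos fail loudly rather than being ignored.
#'
#' @param path YAML file path.
#' @param config A named list restricted to the known keys.
#' @return `readRunConfig` returns the named list; `writeRunConfig` returns
#'   `path` invisibly.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .runConfigKeys)
  .assert(length(unknown) == 0L, "ConfigError",
          "unknown run-config keys: %s", paste(unknown, collapse = ", "))
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  unknown <- setdiff(names(config), .runConfigKeys)
  .assert(length(unknown) == 0L, "ConfigError",
          "unknown run-config keys: %s", paste(unknown, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}
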