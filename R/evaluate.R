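#' Detection / classification metrics report
#'
#' Confusion counts plus the derived metrics.  Precision is `tp/(tp+fp)`
#' and recall `tp/(tp+fn)`; either is `NA` (flagged in `undefined`) when its
#' denominator is zero.  F1 is computed from the unrounded precision and
#' recall.  `tn` and `accuracy` are `NA` for detection reports, where true
#' negatives are not defined.
#'
#' @slot tp,fp,fn,tn Confusion counts (`tn` may be NA).
#' @slot precision,recall,f1,accuracy Derived metrics in `[0, 1]`, NA where
#'   undefined.
#' @slot undefined Character vector naming the undefined metrics.
#' @aliases MetricsReport-class
#' @exportClass MetricsReport
setClass("MetricsReport", representation(
  tp = "integer", fp = "integer", fn = "integer", tn = "integer",
  precision = "numeric", recall = "numeric", f1 = "numeric",
  accuracy = "numeric", undefined = "character"))

.metricsReport <- function(tp, fp, fn, tn = NA_integer_) {
  undef <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undef <- c(undef, "precision"); NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undef <- c(undef, "recall"); NA_real_
  }
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else {
      undef <- c(undef, "f1"); NA_real_
    }
  accuracy <- if (!is.na(tn)) (tp + tn) / (tp + fp + fn + tn) else NA_real_
  new("MetricsReport", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn), precision = precision,
      recall = recall, f1 = f1, accuracy = accuracy, undefined = undef)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: TP %d  FP %d  FN %d%s\n", object@tp,
              object@fp, object@fn,
              if (is.na(object@tn)) "" else sprintf("  TN %d", object@tn)))
  fmt <- function(x) if (is.na(x)) "undef" else sprintf("%.3f", x)
  if (!is.na(object@accuracy))
    cat(sprintf("  accuracy  %s\n", fmt(object@accuracy)))
  cat(sprintf("  precision %s\n  recall    %s\n  F1        %s\n",
              fmt(object@precision), fmt(object@recall), fmt(object@f1)))
})

#' @rdname MetricsReport-class
#' @param object A `MetricsReport`.
#' @export
metricsAsList <- function(object) {
  list(tp = object@tp, fp = object@fp, fn = object@fn, tn = object@tn,
       precision = object@precision, recall = object@recall,
       f1 = object@f1, accuracy = object@accuracy,
       undefined = object@undefined)
}

#' Match detections against ground-truth boxes
#'
#' Greedy one-to-one matching per image: predictions are visited in
#' decreasing confidence (stable order on ties) and each claims the
#' still-unmatched truth box of highest IoU; a prediction is a true positive
#' iff its claimed IoU is at least `iouThreshold`.  Unmatched predictions
#' count as false positives, unmatched truths as false negatives.
#'
#' @param preds Named list (by image id), each element a list of
#'   [DetectionResult-class] objects (possibly empty).
#' @param truths Named list (by image id) of `BoundingBox` objects or lists
#'   of them.  Ids must coincide with `preds` (a `KeyError` is signalled
#'   otherwise).
#' @param iouThreshold Minimum IoU for a true positive (default 0.5).
#' @return A [MetricsReport-class] (detection flavor: no `tn`/accuracy).
#' @export
matchDetections <- function(preds, truths, iouThreshold = 0.5) {
  .assert(setequal(names(preds), names(truths)) &&
            !is.null(names(preds)), "KeyError",
          "prediction and truth image ids do not match")
  tp <- 0L; fp <- 0L; fn <- 0L
  for (id in names(truths)) {
    tr <- truths[[id]]
    if (is(tr, "BoundingBox")) tr <- list(tr)
    pr <- preds[[id]]
    conf <- vapply(pr, detectionConfidence, numeric(1L))
    used <- rep(FALSE, length(tr))
    for (k in order(-conf, seq_along(conf))) {
      ious <- vapply(seq_along(tr), function(j)
        if (used[j]) -1 else iou(detectionBox(pr[[k]]), tr[[j]]),
        numeric(1L))
      j <- if (length(ious)) which.max(ious) else 0L
      if (j > 0L && ious[j] >= iouThreshold && ious[j] > 0) {
        used[j] <- TRUE
        tp <- tp + 1L
      } else {
        fp <- fp + 1L
      }
    }
    fn <- fn + sum(!used)
  }
  .metricsReport(tp, fp, fn)
}

#' Classification metrics from label vectors
#'
#' Tallies the confusion matrix of predicted versus true binary labels and
#' derives accuracy, precision, recall and F1 (undefined metrics are NA and
#' flagged, e.g. when a model never predicts the positive class).
#'
#' @param labels,preds Logical vectors of equal length (a `LengthError` is
#'   signalled otherwise).
#' @return A [MetricsReport-class].
#' @examples
#' classificationMetrics(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
classificationMetrics <- function(labels, preds) {
  .assert(length(labels) == length(preds), "LengthError",
          "labels (%d) and predictions (%d) differ in length",
          length(labels), length(preds))
  labels <- as.logical(labels); preds <- as.logical(preds)
  .metricsReport(tp = sum(labels & preds), fp = sum(!labels & preds),
                 fn = sum(labels & !preds), tn = sum(!labels & !preds))
}

## Split units: groups (keeping variants/duplicates with their original)
## or individual records.
.splitUnits <- function(records, groupAware) {
  if (groupAware) unique(records$group) else records$image_id
}

#' Split a manifest into train/validation/test
#'
#' Seeded shuffle followed by contiguous partition.  All splits except the
#' first receive `floor(fraction * n)` units; the first (training) split
#' receives the remainder, so no unit is lost.  With `groupAware = TRUE`
#' (default) the unit is the `group` — an original together with its
#' augmented variants and duplicates — which prevents augmented copies of a
#' test image from leaking into training; `groupAware = FALSE` splits
#' records independently, the regime in which augmentation precedes the
#' split.
#'
#' @param manifest An `EchoManifest`.
#' @param fractions Numeric fractions summing to 1; names become the split
#'   labels (defaults: `train/val/test` for 3, `train/test` for 2).
#' @param seed Integer seed for the shuffle.
#' @param groupAware Keep groups together (default TRUE).
#' @return The manifest with its `split` column assigned.
#' @export
splitManifest <- function(manifest, fractions = c(0.8, 0.1, 0.1), seed = 0,
                          groupAware = TRUE) {
  .assert(abs(sum(fractions) - 1) < 1e-8 && all(fractions >= 0),
          "ValueError", "fractions must be non-negative and sum to 1")
  if (is.null(names(fractions)))
    names(fractions) <- switch(as.character(length(fractions)),
                               "2" = c("train", "test"),
                               "3" = c("train", "val", "test"),
                               paste0("split", seq_along(fractions)))
  r <- manifestRecords(manifest)
  units <- .splitUnits(r, groupAware)
  set.seed(seed)
  units <- sample(units)
  n <- length(units)
  sizes <- floor(fractions * n)
  sizes[1L] <- n - sum(sizes[-1L])
  assignment <- rep(names(fractions), sizes)
  key <- if (groupAware) r$group else r$image_id
  r$split <- assignment[match(key, units)]
  EchoManifest(r)
}

#' K-fold partition of a manifest
#'
#' Seeded shuffle, then `k` disjoint folds covering the manifest, balanced
#' to within one unit (the first `n %% k` folds get the extra unit).
#'
#' @inheritParams splitManifest
#' @param k Number of folds, `>= 2`.
#' @return A list of `k` `EchoManifest` folds.
#' @export
kfold <- function(manifest, k, seed = 0, groupAware = TRUE) {
  .assert(k >= 2L, "ValueError", "k must be >= 2")
  r <- manifestRecords(manifest)
  units <- .splitUnits(r, groupAware)
  .assert(length(units) >= k, "ValueError",
          "cannot make %d folds from %d units", k, length(units))
  set.seed(seed)
  units <- sample(units)
  n <- length(units)
  sizes <- rep(n %/% k, k) + rep(c(1L, 0L), c(n %% k, k - n %% k))
  foldOf <- rep(seq_len(k), sizes)
  key <- if (groupAware) r$group else r$image_id
  lapply(seq_len(k), function(f)
    EchoManifest(r[foldOf[match(key, units)] == f, , drop = FALSE]))
}
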