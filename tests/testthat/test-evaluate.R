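test_that("classificationMetrics matches a hand-tallied confusion matrix", {
  m <- classificationMetrics(c(TRUE, TRUE, FALSE, FALSE, TRUE),
                             c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(m@tp, 2L); expect_equal(m@fp, 1L)
  expect_equal(m@fn, 1L); expect_equal(m@tn, 1L)
  expect_equal(m@precision, 2 / 3)
  expect_equal(m@recall, 2 / 3)
  expect_equal(m@f1, 2 / 3)
  expect_equal(m@accuracy, 3 / 5)
  expect_length(m@undefined, 0L)
  expect_error(classificationMetrics(c(TRUE), c(TRUE, FALSE)),
               class = "LengthError")
})

test_that("undefined metrics are NA and flagged, never 0/0", {
  # never predicts positive: precision undefined, recall 0
  m <- classificationMetrics(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(m@precision))
  expect_equal(m@recall, 0)
  expect_true(all(c("precision", "f1") %in% m@undefined))
  # no positives at all: recall undefined too
  m2 <- classificationMetrics(c(FALSE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(m2@recall))
  expect_setequal(m2@undefined, c("precision", "recall", "f1"))
  expect_equal(m2@accuracy, 1)
})

test_that("F1 comes from unrounded precision and recall", {
  m <- classificationMetrics(rep(c(TRUE, FALSE), c(9, 14)),
                             c(rep(TRUE, 4), rep(FALSE, 19)))
  # P = 4/4 = 1, R = 4/9; F1 = 2*(4/9)/(1 + 4/9)
  expect_equal(m@f1, 2 * (4 / 9) / (1 + 4 / 9))
})

test_that("matchDetections performs greedy one-to-one matching", {
  mkDet <- function(conf, b) new("DetectionResult", box = b,
                                 confidence = conf)
  tA <- BoundingBox(0, 0, 10, 10)
  tB <- BoundingBox(20, 0, 30, 10)
  # high-confidence pred claims its best truth first; second pred must take
  # the remaining truth; third overlaps nothing
  preds <- list(img1 = list(mkDet(0.9, BoundingBox(1, 0, 11, 10)),
                            mkDet(0.8, BoundingBox(21, 0, 31, 10)),
                            mkDet(0.7, BoundingBox(50, 50, 60, 60))))
  truths <- list(img1 = list(tA, tB))
  m <- matchDetections(preds, truths, iouThreshold = 0.5)
  expect_equal(c(m@tp, m@fp, m@fn), c(2L, 1L, 0L))
  expect_true(is.na(m@tn))
  expect_true(is.na(m@accuracy))

  # two predictions on one truth: only one true positive (one-to-one)
  preds2 <- list(img1 = list(mkDet(0.9, tA), mkDet(0.8, tA)))
  truths2 <- list(img1 = tA)
  m2 <- matchDetections(preds2, truths2)
  expect_equal(c(m2@tp, m2@fp, m2@fn), c(1L, 1L, 0L))

  # missed truth counts as a false negative; empty preds allowed
  m3 <- matchDetections(list(img1 = list()), list(img1 = tA))
  expect_equal(c(m3@tp, m3@fp, m3@fn), c(0L, 0L, 1L))
  expect_true(is.na(m3@precision))

  expect_error(matchDetections(list(a = list()), list(b = tA)),
               class = "KeyError")
})

test_that("greedy matching visits predictions by decreasing confidence", {
  mkDet <- function(conf, b) new("DetectionResult", box = b,
                                 confidence = conf)
  truth <- BoundingBox(0, 0, 10, 10)
  # the low-IoU high-confidence pred claims the truth, leaving the better
  # box unmatched: exactly the documented greedy (not optimal) behavior
  preds <- list(i = list(mkDet(0.5, truth),
                         mkDet(0.9, BoundingBox(4, 0, 14, 10))))
  m <- matchDetections(preds, list(i = truth), iouThreshold = 0.4)
  expect_equal(c(m@tp, m@fp), c(1L, 1L))
})

test_that("splitManifest allocates floors to later splits, rest to train", {
  m <- smallDataset()  # 10 groups
  sp <- splitManifest(m, c(0.8, 0.1, 0.1), seed = 1)
  tab <- table(manifestRecords(sp)$split)
  expect_equal(as.integer(tab[c("train", "val", "test")]), c(8L, 1L, 1L))
  # two-way split default names
  sp2 <- splitManifest(m, c(0.8, 0.2), seed = 1)
  expect_setequal(unique(manifestRecords(sp2)$split), c("train", "test"))
  expect_error(splitManifest(m, c(0.7, 0.2)), class = "ValueError")
  # same seed, same assignment
  sp3 <- splitManifest(m, c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(manifestRecords(sp)$split, manifestRecords(sp3)$split)
})

test_that("group-aware splitting keeps variants and duplicates together", {
  m <- smallDataset()
  ba <- augmentDataset(balanceByDuplication(m), "rotation")
  sp <- splitManifest(ba, c(0.8, 0.2), seed = 5)
  r <- manifestRecords(sp)
  perGroup <- tapply(r$split, r$group, function(s) length(unique(s)))
  expect_true(all(perGroup == 1L))
  # record-level splitting can separate them
  sp2 <- splitManifest(ba, c(0.8, 0.2), seed = 5, groupAware = FALSE)
  r2 <- manifestRecords(sp2)
  expect_equal(sum(r2$split == "test"), floor(0.2 * nSamples(ba)))
})

test_that("kfold balances folds to within one unit and covers everything", {
  m <- smallDataset()
  folds <- kfold(m, 3, seed = 2)
  sizes <- vapply(folds, nSamples, integer(1))
  expect_equal(sort(sizes, decreasing = TRUE), c(4L, 3L, 3L))
  ids <- unlist(lapply(folds, function(f) manifestRecords(f)$image_id))
  expect_setequal(ids, manifestRecords(m)$image_id)
  expect_equal(anyDuplicated(ids), 0L)
  expect_error(kfold(m, 1), class = "ValueError")
  expect_error(kfold(m, 99), class = "ValueError")
})
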