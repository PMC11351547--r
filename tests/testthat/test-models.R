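test_that("model configurations validate their fields", {
  expect_error(DetectorConfig(split = c(0.5, 0.1)), "split")
  expect_error(DetectorConfig(epochs = 0), "epochs")
  expect_error(ClassifierConfig(backboneId = "nope"), "backboneId")
  # a config whose fields were corrupted after construction is caught by
  # buildClassifier with a typed ConfigError
  bad <- ClassifierConfig()
  bad@backboneId <- "nope"
  expect_error(buildClassifier(bad), class = "ConfigError")
  bad2 <- ClassifierConfig()
  bad2@pooling <- "sum"
  expect_error(buildClassifier(bad2), class = "ConfigError")
})

test_that("classifier feature lengths follow the pooling contract", {
  # pooling none: grid^2 x channels; max/avg: one value per channel
  expect_equal(classifierFeatureLength(
    buildClassifier(ClassifierConfig(backboneId = "pool-8",
                                     pooling = "none"))), 8^2 * 5L)
  expect_equal(classifierFeatureLength(
    buildClassifier(ClassifierConfig(backboneId = "pool-4",
                                     pooling = "avg"))), 5L)
  expect_equal(classifierFeatureLength(
    buildClassifier(ClassifierConfig(backboneId = "grad-16",
                                     pooling = "max"))), 7L)
  expect_equal(classifierFeatureLength(
    buildClassifier(ClassifierConfig(backboneId = "grad-4",
                                     pooling = "none"))), 4^2 * 7L)
})

test_that("an untrained classifier maps any region to a probability", {
  clf <- buildClassifier(ClassifierConfig(backboneId = "pool-4",
                                          pooling = "avg"))
  set.seed(6)
  for (k in 1:5) {
    roi <- matrix(sample(0:255, 40 * 50, TRUE), 40, 50)
    p <- calcifiedProbability(classifyRoi(clf, roi))
    expect_gt(p, 0); expect_lt(p, 1)
  }
})

test_that("detector training loss decreases on easy scenes", {
  det <- smokeDetector()
  log <- trainingLossLog(det)
  expect_equal(nrow(log), 40L)
  expect_lt(log$loss[nrow(log)], log$loss[1])
})

test_that("detector training is deterministic under its seed", {
  m <- smallDataset()
  d1 <- trainDetector(m, config = DetectorConfig(epochs = 3, seed = 9))
  d2 <- trainDetector(m, config = DetectorConfig(epochs = 3, seed = 9))
  expect_identical(trainingLossLog(d1), trainingLossLog(d2))
  expect_identical(d1@net$W2, d2@net$W2)
})

test_that("classifier training is deterministic and logs its loss", {
  m <- smallDataset()
  cfg <- ClassifierConfig(epochs = 5, seed = 3, backboneId = "pool-4",
                          pooling = "avg")
  c1 <- trainClassifier(m, cfg)
  c2 <- trainClassifier(m, cfg)
  expect_identical(c1@net$W2, c2@net$W2)
  expect_equal(nrow(c1@lossLog), 5L)
  expect_lt(c1@lossLog$loss[5], c1@lossLog$loss[1])
})

test_that("a single-class training split warns", {
  m <- smallDataset()
  onlyNeg <- m[which(!manifestRecords(m)$calcified)]
  expect_warning(trainClassifier(onlyNeg,
                                 ClassifierConfig(epochs = 2,
                                                  backboneId = "pool-4",
                                                  pooling = "avg")),
                 "single class")
})

test_that("detectValve on an all-zero image returns an empty list", {
  det <- smokeDetector()
  expect_identical(detectValve(det, matrix(0, 128, 128)), list())
})

test_that("selectBest keeps the top detection with stable tie-break", {
  mk <- function(conf, x) new("DetectionResult",
                              box = BoundingBox(x, 0, x + 10, 10),
                              confidence = conf)
  expect_null(selectBest(list()))
  best <- selectBest(list(mk(0.4, 0), mk(0.9, 20)))
  expect_equal(detectionConfidence(best), 0.9)
  # duplicate confidences: first in the list wins
  tied <- selectBest(list(mk(0.7, 0), mk(0.7, 20)))
  expect_equal(detectionBox(tied)@xmin, 0L)
})

test_that("the smoke detector localizes the easy scene it was built for", {
  det <- smokeDetector()
  sc <- easyScene()$scene
  best <- selectBest(detectValve(det, sc$image))
  expect_s4_class(best, "DetectionResult")
  expect_gt(iou(detectionBox(best), sc$truth$valveBox), 0.5)
})
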