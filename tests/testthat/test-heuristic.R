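test_that("heuristicBinarize is strict-threshold and two-valued", {
  expect_equal(heuristicBinarize(matrix(c(0, 220, 221), 1), 220),
               matrix(c(0, 0, 255), 1))
  set.seed(12)
  img <- matrix(sample(0:255, 900, TRUE), 30, 30)
  out <- heuristicBinarize(img, 190)
  expect_true(all(out %in% c(0, 255)))
  expect_equal(out == 255, img > 190)
})

test_that("heuristicBinarize is monotone in the threshold", {
  set.seed(13)
  img <- matrix(sample(0:255, 400, TRUE), 20, 20)
  prev <- NULL
  for (t in c(150, 190, 200, 210, 220)) {
    white <- heuristicBinarize(img, t) == 255
    if (!is.null(prev)) expect_true(all(white <= prev))  # subset of previous
    prev <- white
  }
})

test_that("RGB pixels are white only when all channels clear the threshold", {
  img <- array(0, c(1, 2, 3))
  img[1, 1, ] <- c(255, 255, 100)  # one dark channel: not white
  img[1, 2, ] <- c(225, 230, 240)
  out <- heuristicBinarize(img, 220)
  expect_equal(out[1, 1, ], c(0, 0, 0))
  expect_equal(out[1, 2, ], c(255, 255, 255))
})

test_that("heuristicClassify labels on any white pixel", {
  img <- matrix(160, 32, 32)
  expect_false(isCalcified(heuristicClassify(img, 220)))
  img[16, 16] <- 255
  res <- heuristicClassify(img, 220)
  expect_true(isCalcified(res))
  expect_equal(calcifiedProbability(res), 1 / 1024)
  # exactly at the threshold does not count (strict comparison)
  img[16, 16] <- 220
  expect_false(isCalcified(heuristicClassify(img, 220)))
  expect_error(heuristicBinarize(img, 300), class = "ValueError")
})

test_that("ClassificationResult keeps label consistent with the cutoff", {
  r <- echocalc:::ClassificationResult(0.5, cutoff = 0.5)
  expect_true(isCalcified(r))  # >= convention
  expect_equal(calcifiedProbability(r), 0.5)
  expect_false(isCalcified(echocalc:::ClassificationResult(0.49)))
})
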