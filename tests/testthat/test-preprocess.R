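test_that("detectCone recovers the sector parameters of a clean scene", {
  p <- SceneParams(imageSize = 256, speckleSD = 0)
  sc <- generateScene(p)
  cm <- detectCone(sc$image)
  expect_false(usedFallback(cm))
  overlap <- sum(coneMaskRaster(cm) & sectorMask(p)) /
    sum(coneMaskRaster(cm) | sectorMask(p))
  expect_gt(overlap, 0.95)
  expect_lt(max(abs(cm@apex - p@coneApex)), 6)
  expect_lt(max(abs(sort(cm@edgeAngles) -
                      c(-p@coneHalfAngle, p@coneHalfAngle))), 2)
})

test_that("detectCone falls back and errors sensibly", {
  expect_error(detectCone(matrix(0, 64, 64)), class = "DetectionError")
  # a plain bright rectangle has parallel edges: no apex, fallback path
  rect <- matrix(0, 64, 64)
  rect[10:60, 10:60] <- 120
  cm <- detectCone(rect)
  expect_true(usedFallback(cm))
  expect_true(all(coneMaskRaster(cm)[10:60, 10:60]))
})

test_that("maskAndTightCrop masks outside pixels and reports the offset", {
  img <- matrix(7, 40, 60)
  mask <- matrix(FALSE, 40, 60)
  mask[11:30, 21:50] <- TRUE
  out <- maskAndTightCrop(img, mask)
  expect_equal(dim(out$image), c(20, 30))
  expect_equal(unname(out$offset), c(20L, 10L))
  expect_true(all(out$image == 7))
})

test_that("standardizeCrop keeps pixels 1:1, pads, and reports the origin", {
  img <- matrix(seq_len(50 * 70), 50, 70)
  out <- standardizeCrop(img, size = 64,
                         windowCenter = c(35, 25))
  expect_equal(dim(out$image), c(64, 64))
  # window is clamped into the source horizontally, padded vertically
  expect_equal(unname(out$offset)[1], 3L)
  expect_equal(unname(out$offset)[2], -7L)
  # the source is embedded unchanged (no resampling)
  expect_equal(out$image[8:57, 1:64], img[, 4:67])
  # rows outside the source are zero padding
  expect_true(all(out$image[1:7, ] == 0))
  # box arithmetic: source box maps into the window by subtracting offset
  b <- BoundingBox(10, 10, 20, 20)
  shifted <- BoundingBox(b@xmin - out$offset["x"], b@ymin - out$offset["y"],
                         b@xmax - out$offset["x"], b@ymax - out$offset["y"])
  expect_equal(cropRoi(out$image, shifted), cropRoi(img, b))
})

test_that("reduceNoise subtracts the global minimum and is idempotent", {
  expect_equal(reduceNoise(matrix(c(10, 200, 255), 1)),
               matrix(c(0, 190, 245), 1))
  set.seed(3)
  img <- matrix(sample(20:255, 100, TRUE), 10, 10)
  out <- reduceNoise(img)
  expect_equal(min(out), 0)
  expect_identical(reduceNoise(out), out)
  # the subtrahend is a single global scalar
  expect_equal(out, img - min(img))
})
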