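test_that("BoundingBox validity and geometry accessors", {
  b <- BoundingBox(10, 20, 30, 50)
  expect_equal(boxWidth(b), 20L)
  expect_equal(boxHeight(b), 30L)
  expect_equal(boxArea(b), 600)
  expect_equal(boxCenter(b), c(x = 20, y = 35))
  expect_error(BoundingBox(10, 20, 10, 50), "xmax")
  expect_error(BoundingBox(-1, 0, 5, 5), "xmin")
  expect_output(show(b), "BoundingBox \\[10, 30\\) x \\[20, 50\\)")
})

test_that("iou matches hand-computed and pixel-counting oracles", {
  expect_equal(iou(BoundingBox(0, 0, 2, 2), BoundingBox(1, 0, 3, 2)), 1 / 3)
  expect_equal(iou(BoundingBox(0, 0, 2, 2), BoundingBox(5, 5, 7, 7)), 0)
  expect_equal(iou(BoundingBox(3, 4, 9, 11), BoundingBox(3, 4, 9, 11)), 1)
  set.seed(42)
  for (k in 1:25) {
    a <- BoundingBox(sample(0:10, 1), sample(0:10, 1), sample(11:25, 1),
                     sample(11:25, 1))
    b <- BoundingBox(sample(0:10, 1), sample(0:10, 1), sample(11:25, 1),
                     sample(11:25, 1))
    expect_equal(iou(a, b), oraclePixelIoU(a, b))
  }
})

test_that("cropRoi uses half-open pixel semantics and checks bounds", {
  img <- matrix(seq_len(80 * 100), 80, 100)
  roi <- cropRoi(img, BoundingBox(10, 20, 30, 50))
  expect_equal(dim(roi), c(30, 20))
  expect_equal(roi[1, 1], img[21, 11])  # output (0,0) is input (xmin, ymin)
  expect_equal(roi[30, 20], img[50, 30])
  expect_error(cropRoi(img, BoundingBox(90, 0, 101, 10)),
               class = "BoundsError")
  rgb <- array(img, c(80, 100, 3))
  expect_equal(dim(cropRoi(rgb, BoundingBox(0, 0, 5, 4))), c(4, 5, 3))
})

test_that("detector record conversion round-trips within a pixel", {
  rec <- toDetectorRecord(BoundingBox(160, 160, 480, 480), 640, 640)
  expect_equal(unname(rec), c(0, 0.5, 0.5, 0.5, 0.5))
  set.seed(7)
  for (k in 1:20) {
    b <- BoundingBox(sample(0:100, 1), sample(0:100, 1),
                     sample(101:300, 1), sample(101:300, 1))
    back <- fromDetectorRecord(toDetectorRecord(b, 320, 300), 320, 300)
    delta <- c(back@xmin - b@xmin, back@ymin - b@ymin,
               back@xmax - b@xmax, back@ymax - b@ymax)
    expect_lte(max(abs(delta)), 1L)
  }
})
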