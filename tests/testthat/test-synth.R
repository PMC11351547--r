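test_that("generateScene is deterministic under its seed", {
  p <- SceneParams(imageSize = 128, seed = 11)
  a <- generateScene(p)
  b <- generateScene(p)
  expect_identical(a$image, b$image)
  p2 <- SceneParams(imageSize = 128, seed = 12)
  expect_false(identical(a$image, generateScene(p2)$image))
})

test_that("the valve box is the tight box of the painted ring", {
  sc <- easyScene()$scene
  p <- easyScene()$params
  g <- sc$image[, , 1]
  b <- sc$truth$valveBox
  # every ring-level pixel lies inside the box, and each box edge touches one
  ring <- which(g == p@valveLevel, arr.ind = TRUE)
  xs <- ring[, 2] - 1L; ys <- ring[, 1] - 1L
  expect_equal(min(xs), b@xmin)
  expect_equal(max(xs) + 1L, b@xmax)
  expect_equal(min(ys), b@ymin)
  expect_equal(max(ys) + 1L, b@ymax)
  expect_true(sc$truth$calcified)
  expect_gt(sc$truth$blobPixels, 0)
})

test_that("calcium blob peaks reach their stated intensity exactly", {
  sc <- easyScene()$scene
  expect_equal(max(sc$image), 255)
  # healthy scene never exceeds the ring level when noiseless
  ph <- SceneParams(imageSize = 256, speckleSD = 0)
  expect_equal(max(generateScene(ph)$image), ph@valveLevel)
})

test_that("scene geometry violations raise GeometryError", {
  p <- SceneParams(imageSize = 128)
  p@valveCenter <- c(5, 5)  # ring outside the sector
  expect_error(generateScene(p), class = "GeometryError")
  q <- SceneParams(imageSize = 128)
  q@calciumBlobs <- data.frame(x = 2, y = 2, radius = 3, intensity = 255)
  expect_error(generateScene(q), class = "GeometryError")
})

test_that("generateDataset writes images, annotations, and ground truth", {
  m <- smallDataset()
  r <- manifestRecords(m)
  expect_equal(nSamples(m), 10L)
  expect_equal(sum(r$calcified), 4L)
  expect_true(all(file.exists(r$path)))
  expect_true(all(grepl("^STUDY_\\d{3}$", r$image_id)))
  d <- dirname(r$path[1])
  ann <- readAnnotationsCsv(file.path(d, "annotations.csv"))
  expect_equal(ann$x_min, r$x_min)
  gt <- read.csv(file.path(d, "ground_truth.csv"))
  expect_equal(gt$calcified[match(r$image_id, gt$image_id)], r$calcified)
  # calcified scenes have bright blob pixels, healthy ones none
  expect_true(all((gt$blob_pixels > 0) == gt$calcified))
  # boxes match the stored pixels: ring is visible inside each box
  s <- loadSample(m, 1)
  expect_equal(dim(s$image)[1:2], c(192L, 192L))
  expect_s4_class(s$box, "BoundingBox")
})
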