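test_that("translateImage shifts pixels and box by the rounded fraction", {
  img <- matrix(0, 50, 40)
  img[21, 11] <- 200  # pixel (x=10, y=20)
  out <- translateImage(img, BoundingBox(10, 20, 14, 24), 0.1)
  # dx = round(0.1*40) = 4, dy = round(0.1*50) = 5
  expect_equal(out$image[26, 15], 200)
  expect_equal(out$image[21, 11], 0)
  expect_equal(.boxToVec(out$box), c(xmin = 14L, ymin = 25L,
                                     xmax = 18L, ymax = 29L))
  expect_error(translateImage(img, BoundingBox(0, 0, 2, 2), -0.5),
               class = "BoxLostError")
  expect_error(translateImage(img, NULL, 1.5), class = "ValueError")
})

test_that("gammaContrast applies the exact power-law formula", {
  set.seed(4)
  img <- matrix(sample(0:255, 400, TRUE), 20, 20)
  for (g in c(0.5, 1.2, 2, 0.8)) {
    out <- gammaContrast(img, NULL, g)$image
    expect_equal(out, matrix(round(255 * (img / 255)^g), 20, 20))
  }
  b <- BoundingBox(2, 2, 8, 8)
  expect_identical(gammaContrast(img, b, 0.5)$box, b)
  expect_error(gammaContrast(img, NULL, 0), class = "ValueError")
})

test_that("zoom and rotation boxes match the mask-transform oracle", {
  for (cs in randomBoxCases(20, seed = 55)) {
    out <- switch(cs$technique,
                  translation = translateImage(matrix(0, cs$h, cs$w),
                                               cs$box, cs$p),
                  zoom = zoomImage(matrix(0, cs$h, cs$w), cs$box, cs$p),
                  rotation = rotateImage(matrix(0, cs$h, cs$w), cs$box, cs$p))
    expect_lte(max(abs(.boxToVec(out$box) - cs$oracle)), 2)
  }
})

test_that("warped pixels follow the box: a bright patch stays inside", {
  img <- matrix(0, 80, 80)
  img[31:40, 31:40] <- 250
  b <- BoundingBox(30, 30, 40, 40)
  for (op in list(function() zoomImage(img, b, 1.3),
                  function() rotateImage(img, b, 10),
                  function() translateImage(img, b, 0.1))) {
    out <- op()
    bright <- which(out$image > 125, arr.ind = TRUE)
    expect_true(all(bright[, 2] - 1 >= out$box@xmin &
                      bright[, 2] - 1 < out$box@xmax &
                      bright[, 1] - 1 >= out$box@ymin &
                      bright[, 1] - 1 < out$box@ymax))
  }
})

test_that("augmentDataset obeys the n * (1 + 2 * techniques) count law", {
  m <- smallDataset()
  n <- nSamples(m)
  expect_equal(nSamples(augmentDataset(m, "rotation")), n * 3L)
  expect_equal(nSamples(augmentDataset(m, c("translation", "rotation"))),
               n * 5L)
  all4 <- augmentDataset(m, c("translation", "zoom", "rotation", "gamma"))
  expect_equal(nSamples(all4), n * 9L)
  r <- manifestRecords(all4)
  expect_equal(sum(is.na(r$technique)), n)
  # variants keep their original's group and label
  expect_equal(r$group, sub("_(tr|zm|rot|gm).*$", "", r$image_id))
  # re-augmenting augmented variants is refused
  expect_error(augmentDataset(all4, "gamma"), class = "ValueError")
  # non-standard parameters need custom = TRUE
  expect_error(augmentDataset(m, "rotation", params = list(rotation = c(5, -5))),
               class = "ValueError")
  custom <- augmentDataset(m, "rotation", params = list(rotation = c(5, -5)),
                           custom = TRUE)
  expect_equal(nSamples(custom), n * 3L)
})

test_that("lazy variants materialize to the same pixels as direct operators", {
  m <- smallDataset()
  a <- augmentDataset(m, c("rotation", "gamma"))
  r <- manifestRecords(a)
  orig <- loadSample(m, 1)
  for (tag in c("rot10", "gm0p5")) {
    i <- which(r$image_id == paste0(orig$image_id, "_", tag))
    expect_length(i, 1L)
    v <- loadSample(a, i)
    direct <- if (tag == "rot10") rotateImage(orig$image, orig$box, 10)
              else gammaContrast(orig$image, orig$box, 0.5)
    expect_equal(v$image, direct$image)
    expect_equal(.boxToVec(v$box), .boxToVec(direct$box))
  }
})

test_that("balanceByDuplication equalizes classes by cyclic duplication", {
  m <- smallDataset()  # 4 calcified / 6 healthy
  b <- balanceByDuplication(m)
  r <- manifestRecords(b)
  expect_equal(nSamples(b), 12L)
  expect_equal(sum(r$calcified), 6L)
  dup <- r[!is.na(r$duplicate_of), ]
  expect_equal(nrow(dup), 2L)
  expect_true(all(dup$calcified))
  expect_true(all(grepl("_dup1$", dup$image_id)))
  # duplicates share their original's group
  expect_equal(dup$group, dup$duplicate_of)
  # balanced input is returned unchanged; single-class input errors
  expect_identical(nSamples(balanceByDuplication(b)), 12L)
  onlyNeg <- m[which(!manifestRecords(m)$calcified)]
  expect_error(balanceByDuplication(onlyNeg), class = "BalanceError")
})
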