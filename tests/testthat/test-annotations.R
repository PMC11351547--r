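test_that("annotation CSV writing then reading reproduces records exactly", {
  set.seed(21)
  for (k in 1:10) {
    n <- sample(1:8, 1)
    recs <- data.frame(
      image_id = sprintf("STUDY_%03d", seq_len(n) - 1L),
      x_min = sample(0:50, n, TRUE), y_min = sample(0:50, n, TRUE),
      stringsAsFactors = FALSE)
    recs$x_max <- recs$x_min + sample(1:80, n, TRUE)
    recs$y_max <- recs$y_min + sample(1:80, n, TRUE)
    f <- tempfile(fileext = ".csv")
    writeAnnotationsCsv(recs, f)
    back <- readAnnotationsCsv(f)
    for (col in names(recs)[-1]) back[[col]] <- as.integer(back[[col]])
    recs[-1] <- lapply(recs[-1], as.integer)
    expect_identical(back, recs)
  }
})

test_that("annotation schema and value errors are typed", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(image_id = "a", x_min = 1), f, row.names = FALSE)
  expect_error(readAnnotationsCsv(f), class = "SchemaError")
  write.csv(data.frame(image_id = "a", x_min = 10, y_min = 0,
                       x_max = 5, y_max = 5), f, row.names = FALSE)
  expect_error(readAnnotationsCsv(f), class = "ValueError")
  expect_error(writeAnnotationsCsv(data.frame(image_id = "a"), f),
               class = "SchemaError")
})

test_that("writeDetectorLabels emits one normalized record per image", {
  m <- smallDataset()
  d <- tempfile()
  files <- writeDetectorLabels(m, d, 192, 192)
  r <- manifestRecords(m)
  expect_length(files, nSamples(m))
  line <- readLines(file.path(d, paste0(r$image_id[1], ".txt")))
  v <- as.numeric(strsplit(line, " ")[[1]])
  expect_equal(v[1], 0)
  expected <- toDetectorRecord(BoundingBox(r$x_min[1], r$y_min[1],
                                           r$x_max[1], r$y_max[1]), 192, 192)
  expect_equal(v[-1], unname(expected[-1]), tolerance = 1e-5)
  expect_true(all(v[-1] >= 0 & v[-1] <= 1))
})
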