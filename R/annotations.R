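#' Read and write valve annotations as CSV
#'
#' Annotations are persisted as a plain CSV with header
#' `image_id,x_min,y_min,x_max,y_max`, one manually drawn valve rectangle per
#' image in 0-based half-open pixel coordinates.  Writing then reading
#' reproduces the records exactly.
#'
#' @param path CSV file path.
#' @param records A data.frame with columns `image_id, x_min, y_min, x_max,
#'   y_max` (extra columns are dropped on write), or an `EchoManifest`.
#' @return `readAnnotationsCsv` returns a data.frame with the five schema
#'   columns (zero rows for a header-only file); `writeAnnotationsCsv`
#'   returns `path` invisibly.
#' @examples
#' recs <- data.frame(image_id = "STUDY_000",
#'                    x_min = 100L, y_min = 120L, x_max = 200L, y_max = 210L)
#' f <- tempfile(fileext = ".csv")
#' writeAnnotationsCsv(recs, f)
#' identical(readAnnotationsCsv(f), recs)
#' @export
readAnnotationsCsv <- function(path) {
  ann <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("image_id", "x_min", "y_min", "x_max", "y_max")
  missing <- setdiff(cols, names(ann))
  .assert(length(missing) == 0L, "SchemaError",
          "annotation CSV is missing columns: %s",
          paste(missing, collapse = ", "))
  ann <- ann[, cols]
  for (col in cols[-1L]) ann[[col]] <- as.integer(ann[[col]])
  bad <- ann$x_max <= ann$x_min | ann$y_max <= ann$y_min |
    ann$x_min < 0L | ann$y_min < 0L
  .assert(!any(bad), "ValueError",
          "inverted or negative box coordinates for: %s",
          paste(ann$image_id[bad], collapse = ", "))
  ann
}

#' @rdname readAnnotationsCsv
#' @export
writeAnnotationsCsv <- function(records, path) {
  if (is(records, "EchoManifest")) records <- manifestRecords(records)
  cols <- c("image_id", "x_min", "y_min", "x_max", "y_max")
  missing <- setdiff(cols, names(records))
  .assert(length(missing) == 0L, "SchemaError",
          "annotation records are missing columns: %s",
          paste(missing, collapse = ", "))
  out <- records[, cols]
  out <- out[!is.na(out$x_min), , drop = FALSE]
  bad <- out$x_max <= out$x_min | out$y_max <= out$y_min
  .assert(!any(bad), "ValueError",
          "inverted box coordinates for: %s",
          paste(out$image_id[bad], collapse = ", "))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export annotations in the detector's per-image text format
#'
#' Writes one `<image_id>.txt` per annotated image under `dir`, each line
#' `class cx cy w h` normalized to the image extent (class 0, the single
#' aortic-valve class), the format [trainDetector()] datasets use on disk.
#'
#' @param manifest An `EchoManifest` (or annotation data.frame plus image
#'   sizes via `imageW`/`imageH`).
#' @param dir Output directory (created if needed).
#' @param imageW,imageH Image extent; a single pair applied to all records.
#' @return Invisibly, the vector of files written.
#' @export
writeDetectorLabels <- function(manifest, dir, imageW, imageH) {
  if (is(manifest, "EchoManifest")) manifest <- manifestRecords(manifest)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- which(!is.na(manifest$x_min))
  files <- character(0)
  for (i in rows) {
    rec <- manifest[i, ]
    box <- BoundingBox(rec$x_min, rec$y_min, rec$x_max, rec$y_max)
    v <- toDetectorRecord(box, imageW, imageH)
    f <- file.path(dir, paste0(rec$image_id, ".txt"))
    writeLines(sprintf("%d %.6f %.6f %.6f %.6f", as.integer(v[1L]),
                       v[2L], v[3L], v[4L], v[5L]), f)
    files <- c(files, f)
  }
  invisible(files)
}
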