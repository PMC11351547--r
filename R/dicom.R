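## Minimal DICOM reading: explicit-VR little-endian files with uncompressed
## 8-bit pixel data, which covers the exported cine loops this pipeline
## consumes.  Only the handful of tags the pipeline needs are interpreted;
## the whole patient group (0010,xxxx) is dropped so no identifying
## metadata can propagate.

.u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
.u32 <- function(raw, at) {
  as.numeric(raw[at]) + 256 * as.numeric(raw[at + 1L]) +
    65536 * as.numeric(raw[at + 2L]) + 16777216 * as.numeric(raw[at + 3L])
}

.longLengthVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

## Parse all top-level data elements of an explicit-VR little-endian stream.
.parseDicomElements <- function(raw, at) {
  elems <- list()
  n <- length(raw)
  while (at + 7L <= n) {
    group <- .u16(raw, at); elem <- .u16(raw, at + 2L)
    vr <- rawToChar(raw[(at + 4L):(at + 5L)])
    if (vr %in% .longLengthVRs) {
      len <- .u32(raw, at + 8L)
      at <- at + 12L
    } else {
      len <- .u16(raw, at + 6L)
      at <- at + 8L
    }
    if (at + len - 1L > n) break
    value <- if (len > 0) raw[at:(at + len - 1L)] else raw(0)
    at <- at + len
    elems[[length(elems) + 1L]] <- list(group = group, elem = elem,
                                        vr = vr, value = value)
    if (group == 0x7FE0L && elem == 0x0010L) break  # pixel data is last
  }
  elems
}

.dicomString <- function(x) {
  v <- x$value
  while (length(v) && v[length(v)] %in% as.raw(c(0L, 32L)))
    v <- v[-length(v)]
  rawToChar(v)
}

#' Extract anonymized frames from a DICOM file
#'
#' Reads an explicit-VR little-endian DICOM file with uncompressed 8-bit
#' pixel data and returns its frames as 8-bit RGB arrays under sequential
#' anonymized ids (`STUDY_000`, `STUDY_001`, ...).  No element of the
#' patient group (names, birth dates, ids) is read or propagated; the
#' returned metadata is limited to image-geometry tags.
#'
#' @param path DICOM file path.
#' @param idOffset First sequential number to use for the ids (default 0).
#' @return A list with one element per frame, each a list with `image`
#'   (H x W x 3 array, 0-255) and `id`; the attribute `metadata` holds a
#'   named list of the retained non-identifying tags.  Signals a
#'   `FormatError` for non-DICOM input or files without 8-bit pixel data.
#' @export
extractDicomFrames <- function(path, idOffset = 0) {
  raw <- readBin(path, "raw", file.size(path))
  .assert(length(raw) > 132L &&
            rawToChar(raw[129:132]) == "DICM", "FormatError",
          "'%s' is not a DICOM file", path)
  elems <- .parseDicomElements(raw, 133L)

  get1 <- function(group, elem) {
    for (e in elems) if (e$group == group && e$elem == elem) return(e)
    NULL
  }
  pix <- get1(0x7FE0L, 0x0010L)
  .assert(!is.null(pix), "FormatError", "no pixel data in '%s'", path)
  rowsE <- get1(0x0028L, 0x0010L); colsE <- get1(0x0028L, 0x0011L)
  .assert(!is.null(rowsE) && !is.null(colsE), "FormatError",
          "missing image dimensions in '%s'", path)
  rows <- .u16(rowsE$value, 1L); cols <- .u16(colsE$value, 1L)
  bits <- get1(0x0028L, 0x0100L)
  if (!is.null(bits))
    .assert(.u16(bits$value, 1L) == 8L, "FormatError",
            "only 8-bit pixel data is supported")
  spp <- get1(0x0028L, 0x0002L)
  samples <- if (is.null(spp)) 1L else .u16(spp$value, 1L)
  nfE <- get1(0x0028L, 0x0008L)
  nframes <- if (is.null(nfE)) 1L else as.integer(.dicomString(nfE))

  frameLen <- rows * cols * samples
  .assert(length(pix$value) >= frameLen * nframes, "FormatError",
          "pixel data shorter than %d frame(s)", nframes)

  meta <- list(rows = rows, columns = cols, samples_per_pixel = samples,
               number_of_frames = nframes)
  frames <- vector("list", nframes)
  for (f in seq_len(nframes)) {
    bytes <- as.integer(pix$value[((f - 1L) * frameLen + 1L):(f * frameLen)])
    img <- if (samples == 1L) {
      .asRGB(matrix(bytes, rows, cols, byrow = TRUE))
    } else {
      a <- array(0, c(rows, cols, samples))
      for (s in seq_len(samples))
        a[, , s] <- matrix(bytes[seq(s, frameLen, by = samples)],
                           rows, cols, byrow = TRUE)
      a
    }
    frames[[f]] <- list(image = img,
                        id = sprintf("STUDY_%03d", idOffset + f - 1L))
  }
  attr(frames, "metadata") <- meta
  frames
}
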