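#' Read and write 8-bit echo images
#'
#' Images are handled throughout the package as plain numeric arrays in 8-bit
#' units: a matrix (grayscale) or an H x W x 3 array (RGB), values in 0-255.
#' `readEchoImage` reads a PNG (alpha, if present, is dropped);
#' `writeEchoImage` writes one.
#'
#' @param path Path of a PNG file.
#' @param image A matrix or H x W x 3 array with values in 0-255.
#' @return `readEchoImage` returns the image array; `writeEchoImage` returns
#'   `path` invisibly.
#' @examples
#' img <- matrix(0:255, 16, 16)
#' f <- tempfile(fileext = ".png")
#' writeEchoImage(img, f)
#' rng <- range(readEchoImage(f))
#' @export
readEchoImage <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  if (length(dim(x)) == 3L && dim(x)[3] == 2L) x <- x[, , 1L]  # gray + alpha
  round(x * 255)
}

#' @rdname readEchoImage
#' @export
writeEchoImage <- function(image, path) {
  image <- pmin(pmax(image, 0), 255)
  png::writePNG(image / 255, path)
  invisible(path)
}

## Grayscale view of an image (mean over channels); identity on matrices.
.asGray <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3L)
  (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
}

## Per-pixel minimum over channels (what "white in all channels" tests).
.channelMin <- function(image) {
  if (is.matrix(image)) return(image)
  pmin(image[, , 1L], image[, , 2L], image[, , 3L])
}

## Replicate a grayscale matrix into 3 identical channels.
.asRGB <- function(image) {
  if (!is.matrix(image)) return(image)
  array(image, dim = c(dim(image), 3L))
}

.imageDim <- function(image) {
  d <- dim(image)
  c(h = d[1L], w = d[2L])
}

## Apply a matrix-level operation to each channel of an image.  The
## operation may change the spatial extent (e.g. cropping to a window);
## the output array takes the extent of the first channel's result.
.perChannel <- function(image, fn) {
  if (is.matrix(image)) return(fn(image))
  nch <- dim(image)[3L]
  chan <- function(k) {
    m <- image[, , k, drop = FALSE]
    dim(m) <- dim(image)[1:2]
    m
  }
  first <- fn(chan(1L))
  out <- array(0, dim = c(dim(first), nch))
  out[, , 1L] <- first
  for (k in seq_len(nch)[-1L]) out[, , k] <- fn(chan(k))
  out
}
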