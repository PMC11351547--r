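# Minimal explicit-VR little-endian DICOM writer, used only to create test
# fixtures for extractDicomFrames().  Written independently of the reader.

writeMinimalDicom <- function(path, frames, patientName = "Doe^Jane") {
  u16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))
  u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  strVal <- function(s) {
    v <- charToRaw(s)
    if (length(v) %% 2L == 1L) v <- c(v, as.raw(32L))
    v
  }
  element <- function(group, elem, vr, value) {
    head <- c(u16(group), u16(elem), charToRaw(vr))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      c(head, as.raw(c(0L, 0L)), u32(length(value)), value)
    } else {
      c(head, u16(length(value)), value)
    }
  }
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  # pixel data is stored row-major
  pix <- as.raw(unlist(lapply(frames, function(m) as.integer(t(m)))))
  body <- c(
    element(0x0010, 0x0010, "PN", strVal(patientName)),
    element(0x0028, 0x0002, "US", u16(1L)),
    element(0x0028, 0x0008, "IS", strVal(as.character(length(frames)))),
    element(0x0028, 0x0010, "US", u16(h)),
    element(0x0028, 0x0011, "US", u16(w)),
    element(0x0028, 0x0100, "US", u16(8L)),
    element(0x7FE0, 0x0010, "OB", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}
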