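# Shared fixtures: small phantom specs and a byte-level DICOM writer used to
# exercise the reader without any binary files in the repository.

smallSpec <- function(...) {
  args <- modifyList(list(imageHeight = 128, imageWidth = 128, noiseSd = 6,
                          seed = 42L), list(...))
  do.call(phantomSpec, args)
}

compressedSpec <- function(fraction = 0.4, index = 3L, ...) {
  smallSpec(compressedIndex = index, compressionFraction = fraction, ...)
}

# Write a minimal single-frame DICOM file, explicit or implicit VR little
# endian, optionally with the 128-byte preamble and file-meta group.
writeTestDicom <- function(path, px, bits = 16L,
                           photometric = "MONOCHROME2",
                           spacing = c(0.14, 0.14), explicit = TRUE,
                           preamble = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  # DICOM values must have even byte length; UI pads with NUL, text with
  # space
  evenRaw <- function(s, nul = FALSE) {
    b <- charToRaw(s)
    if (length(b) %% 2 == 1) b <- c(b, if (nul) as.raw(0) else charToRaw(" "))
    b
  }
  writeTag <- function(group, elem, vr, value) {
    writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
    if (vr %in% c("US",
                  "CS", "DS", "UI", "IS")) {
      if (explicit || group == 0x0002) {
        writeChar(vr, con, 2, eos = NULL)
        lenRaw <- function(n) writeBin(as.integer(n), con, size = 2,
                                       endian = "little")
      } else {
        lenRaw <- function(n) writeBin(as.integer(n), con, size = 4,
                                       endian = "little")
      }
      if (vr == "US") {
        lenRaw(2L)
        writeBin(as.integer(value), con, size = 2, endian = "little")
      } else {
        b <- evenRaw(value, nul = vr == "UI")
        lenRaw(length(b))
        writeBin(b, con)
      }
    } else if (vr == "OW") {
      if (explicit || group == 0x0002) {
        writeChar("OW", con, 2, eos = NULL)
        writeBin(as.integer(0), con, size = 2, endian = "little")
        writeBin(length(value) * (bits %/% 8L), con, size = 4,
                 endian = "little")
      } else {
        writeBin(length(value) * (bits %/% 8L), con, size = 4,
                 endian = "little")
      }
      writeBin(as.integer(value), con, size = bits %/% 8L,
               endian = "little")
    }
  }
  if (preamble) {
    writeBin(raw(128), con)
    writeChar("DICM", con, 4, eos = NULL)
    ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
    # file meta group is always explicit
    writeBin(as.integer(c(0x0002, 0x0010)), con, size = 2,
             endian = "little")
    writeChar("UI", con, 2, eos = NULL)
    b <- evenRaw(ts, nul = TRUE)
    writeBin(as.integer(length(b)), con, size = 2, endian = "little")
    writeBin(b, con)
  }
  writeTag(0x0028, 0x0004, "CS", photometric)
  writeTag(0x0028, 0x0010, "US", nrow(px))
  writeTag(0x0028, 0x0011, "US", ncol(px))
  if (!is.null(spacing))
    writeTag(0x0028, 0x0030, "DS",
             paste(formatC(spacing, format = "f", digits = 4),
                   collapse = "\\"))
  writeTag(0x0028, 0x0100, "US", bits)
  writeTag(0x0028, 0x0103, "US", 0L)
  writeTag(0x7FE0, 0x0010, "OW", as.vector(t(px)))  # row-major pixel order
  invisible(path)
}
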