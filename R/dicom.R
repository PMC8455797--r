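# Minimal single-frame DICOM reader.
#
# Scope: uncompressed little-endian transfer syntaxes only (implicit
# 1.2.840.10008.1.2 and explicit 1.2.840.10008.1.2.1), single-frame
# grayscale, unsigned 8- or 16-bit pixels, MONOCHROME1/2. That covers
# de-identified lateral spine radiographs exported from PACS; anything
# compressed or multi-frame is rejected with a clear message.

isDicomFile <- function(path) {
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) return(TRUE)
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132)
  length(hdr) == 132 && identical(hdr[129:132], charToRaw("DICM"))
}

readU16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
readU32 <- function(raw, at) {
  as.double(readU16(raw, at)) + 65536 * readU16(raw, at + 2L)
}

#' Read a single-frame grayscale DICOM radiograph
#'
#' Parses uncompressed little-endian DICOM (implicit or explicit VR),
#' extracting Rows, Columns, BitsAllocated, PixelSpacing and
#' PhotometricInterpretation. MONOCHROME1 images are inverted so that higher
#' values always mean brighter (MONOCHROME2 convention). Compressed,
#' multi-frame or signed-pixel files are rejected.
#'
#' @param path DICOM file path.
#' @return A \linkS4class{Radiograph} with bit depth 8 or 16.
#' @export
readDicomImage <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  pos <- 1L
  if (length(raw) >= 132 && identical(raw[129:132], charToRaw("DICM")))
    pos <- 133L
  tags <- list()
  explicit <- NA   # resolved when the first non-meta element is reached
  vr16 <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos <= length(raw) - 7L) {
    group <- readU16(raw, pos); elem <- readU16(raw, pos + 2L)
    if (group == 0x0002) {
      exp <- TRUE   # file-meta group is always explicit little endian
    } else {
      if (is.na(explicit)) {
        ts <- tags[["0002,0010"]]
        if (!is.null(ts)) {
          ts <- gsub("[^0-9.]", "", ts)
          if (ts == "1.2.840.10008.1.2") explicit <- FALSE
          else if (ts == "1.2.840.10008.1.2.1") explicit <- TRUE
          else stop("unsupported DICOM transfer syntax: ", ts,
                    " (only uncompressed little endian is supported)")
        } else {
          # no file-meta group: sniff VR mode from the first element
          explicit <- grepl("^[A-Z]{2}$",
                            rawToChar(raw[(pos + 4L):(pos + 5L)]))
        }
      }
      exp <- explicit
    }
    if (exp) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% vr16) {
        len <- readU32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- readU16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- ""; len <- readU32(raw, pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements ",
                                "(sequences/encapsulated data) unsupported")
    valAt <- pos + hdr
    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% c("0002,0010", "0028,0004", "0028,0030")) {
      b <- raw[valAt:(valAt + len - 1L)]
      tags[[key]] <- trimws(rawToChar(b[b != as.raw(0)]))  # strip UI padding
    } else if (key %in% c("0028,0010", "0028,0011", "0028,0100",
                          "0028,0103", "0028,0008")) {
      b <- as.integer(raw[valAt:(valAt + len - 1L)])
      # IS values are ASCII digit strings; US values are binary uint16
      tags[[key]] <- if (len > 0 && all(b %in% c(0L, 32L, 48:57)) &&
                         any(b %in% 48:57) && (vr == "IS" || len != 2L)) {
        as.integer(trimws(rawToChar(as.raw(b[b != 0L]))))
      } else readU16(raw, valAt)
    } else if (key == "7fe0,0010") {
      tags$pixelDataAt <- valAt; tags$pixelDataLen <- len
      break
    }
    pos <- valAt + len
  }
  rows <- tags[["0028,0010"]]; cols <- tags[["0028,0011"]]
  bits <- tags[["0028,0100"]]
  stopIfNot(!is.null(rows) && !is.null(cols) && !is.null(bits) &&
            !is.null(tags$pixelDataAt),
            "not a readable DICOM image (missing Rows/Columns/PixelData)")
  frames <- tags[["0028,0008"]]
  stopIfNot(is.null(frames) || frames <= 1L, "multi-frame DICOM unsupported")
  signed <- tags[["0028,0103"]]
  stopIfNot(is.null(signed) || signed == 0L,
            "signed DICOM pixel data unsupported")
  stopIfNot(bits %in% c(8L, 16L), "BitsAllocated must be 8 or 16, got %d",
            bits)
  n <- rows * cols
  at <- tags$pixelDataAt
  vals <- if (bits == 8L) {
    as.integer(raw[at:(at + n - 1L)])
  } else {
    lo <- as.integer(raw[seq(at, by = 2L, length.out = n)])
    hi <- as.integer(raw[seq(at + 1L, by = 2L, length.out = n)])
    lo + 256 * hi
  }
  px <- matrix(vals, nrow = rows, byrow = TRUE)
  photometric <- tags[["0028,0004"]]
  if (!is.null(photometric) && grepl("MONOCHROME1", photometric))
    px <- (2^bits - 1) - px
  spacing <- numeric(0)
  if (!is.null(tags[["0028,0030"]])) {
    sp <- as.numeric(strsplit(tags[["0028,0030"]], "\\\\")[[1]])
    if (length(sp) == 2 && all(is.finite(sp)) && all(sp > 0)) spacing <- sp
  }
  Radiograph(px, bitDepth = as.integer(bits), pixelSpacing = spacing,
             sourceId = sub("\\.[^.]*$", "", basename(path)))
}
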