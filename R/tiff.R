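# Minimal baseline TIFF codec for multi-frame 8-bit grayscale stacks
# (uncompressed, little-endian, one strip per frame). No TIFF library is
# available in the supported R stack, and the format subset needed for
# kymograph movies is small enough to implement directly. Round-trips are
# validated in the test suite.

.tiff_tag <- function(id, type, count, value) {
  # returns 12 raw bytes; `value` must already fit in 4 bytes
  c(writeBin(as.integer(id), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    writeBin(as.integer(value), raw(), size = 4, endian = "little"))
}

#' Write a frame stack as a multi-frame grayscale TIFF
#'
#' Baseline TIFF: 8-bit grayscale, uncompressed, little-endian, one image
#' file directory per frame. Intensities are clipped to `[0, 1]` and
#' quantized to 0-255.
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  dims <- dim(stack$frames)
  h <- dims[1]; w <- dims[2]; nfr <- dims[3]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  hdr_ifd_ptr <- 4L
  frame_bytes <- h * w
  ifd_bytes <- 2L + 8L * 12L + 4L
  # layout: 8-byte header, then per frame [pixel data][IFD]
  data_off <- function(k) 8L + (k - 1L) * (frame_bytes + ifd_bytes)
  ifd_off <- function(k) data_off(k) + frame_bytes
  writeBin(as.integer(ifd_off(1L)), con, size = 4, endian = "little")
  for (k in seq_len(nfr)) {
    fr <- stack$frames[, , k]
    px <- round(pmin(pmax(fr, 0), 1) * 255)
    # TIFF is row-major (row 1 first); R matrices are column-major
    writeBin(as.raw(as.integer(t(px))), con)
    writeBin(as.integer(8L), con, size = 2, endian = "little")  # 8 tags
    writeBin(.tiff_tag(256, 3, 1, w), con)          # ImageWidth
    writeBin(.tiff_tag(257, 3, 1, h), con)          # ImageLength
    writeBin(.tiff_tag(258, 3, 1, 8), con)          # BitsPerSample
    writeBin(.tiff_tag(259, 3, 1, 1), con)          # Compression: none
    writeBin(.tiff_tag(262, 3, 1, 1), con)          # Photometric: BlackIsZero
    writeBin(.tiff_tag(273, 4, 1, data_off(k)), con)  # StripOffsets
    writeBin(.tiff_tag(278, 3, 1, h), con)          # RowsPerStrip
    writeBin(.tiff_tag(279, 4, 1, frame_bytes), con)  # StripByteCounts
    nxt <- if (k < nfr) ifd_off(k + 1L) else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

.read_u <- function(raw_vec, off, size) {
  # little-endian unsigned integer at 1-based byte offset off+1
  sum(as.integer(raw_vec[off + seq_len(size)]) * 256^(seq_len(size) - 1))
}

#' Read a multi-frame grayscale TIFF as a frame stack
#'
#' Supports the baseline subset written by [write_tiff_stack()]:
#' little-endian, 8-bit grayscale, uncompressed, any number of strips.
#'
#' @param path TIFF file path.
#' @param fps Frame rate to attach (frames/s).
#' @param scale Spatial calibration to attach (um/px).
#' @return A [frame_stack()] with intensities in `[0, 1]`.
#' @export
read_tiff_stack <- function(path, fps, scale) {
  raw_vec <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw_vec[1:2]) != "II" || .read_u(raw_vec, 2, 2) != 42) {
    stop("not a little-endian baseline TIFF", call. = FALSE)
  }
  ifd <- .read_u(raw_vec, 4, 4)
  frames <- list()
  while (ifd != 0) {
    ntag <- .read_u(raw_vec, ifd, 2)
    tags <- list()
    for (i in seq_len(ntag)) {
      base <- ifd + 2 + (i - 1) * 12
      id <- .read_u(raw_vec, base, 2)
      type <- .read_u(raw_vec, base + 2, 2)
      count <- .read_u(raw_vec, base + 4, 4)
      vsize <- c(1, 1, 2, 4, 8)[type]
      if (count * vsize <= 4) {
        vals <- vapply(seq_len(count) - 1,
                       function(j) .read_u(raw_vec, base + 8 + j * vsize,
                                           vsize), 0)
      } else {
        voff <- .read_u(raw_vec, base + 8, 4)
        vals <- vapply(seq_len(count) - 1,
                       function(j) .read_u(raw_vec, voff + j * vsize,
                                           vsize), 0)
      }
      tags[[as.character(id)]] <- vals
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    if (!is.null(tags[["258"]]) && any(tags[["258"]] != 8)) {
      stop("only 8-bit grayscale TIFFs are supported", call. = FALSE)
    }
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1) {
      stop("compressed TIFFs are not supported", call. = FALSE)
    }
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    bytes <- unlist(lapply(seq_along(offs), function(j) {
      raw_vec[offs[j] + seq_len(cnts[j])]
    }))
    m <- matrix(as.integer(bytes), nrow = h, ncol = w, byrow = TRUE)
    frames[[length(frames) + 1L]] <- m / 255
    ifd <- .read_u(raw_vec, ifd + 2 + ntag * 12, 4)
  }
  arr <- array(unlist(frames), dim = c(nrow(frames[[1]]),
                                       ncol(frames[[1]]), length(frames)))
  frame_stack(arr, fps, scale)
}
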