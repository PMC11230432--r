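# Minimal multi-page grayscale TIFF I/O (little-endian, uncompressed,
# 32-bit float). No pre-installed R package reads TIFF in this toolchain,
# so the bright-field interface implements the small baseline subset it
# needs; round-trip fidelity is covered by tests.

.tiff_tag <- function(id, type, count, value) {
  list(id = id, type = type, count = count, value = value)
}

#' Write a z-stack to an uncompressed grayscale TIFF
#'
#' One image-file directory per z-slice, 32-bit float samples,
#' little-endian, single strip per slice.
#'
#' @param stack 3D array (z, y, x) or a matrix (single slice).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(1, dim(stack)))
  stopifnot(length(dim(stack)) == 3)
  nz <- dim(stack)[1]; ny <- dim(stack)[2]; nx <- dim(stack)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  # layout: header (8) | slice data blocks | IFDs
  data_bytes <- nx * ny * 4
  data_off <- 8
  ifd0_off <- 8 + nz * data_bytes
  writeBin(as.integer(ifd0_off), con, size = 4, endian = "little")
  for (z in seq_len(nz)) {
    # row-major pixel order: rows of the (y, x) slice
    writeBin(as.numeric(t(stack[z, , ])[seq_len(nx * ny)]), con, size = 4,
             endian = "little")
  }
  n_tags <- 10L
  ifd_size <- 2 + n_tags * 12 + 4
  for (z in seq_len(nz)) {
    writeBin(n_tags, con, size = 2, endian = "little")
    wtag <- function(id, type, count, value) {
      writeBin(as.integer(id), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3) { # SHORT packed left-justified
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    wtag(256, 4, 1, nx)                         # ImageWidth
    wtag(257, 4, 1, ny)                         # ImageLength
    wtag(258, 3, 1, 32)                         # BitsPerSample
    wtag(259, 3, 1, 1)                          # Compression: none
    wtag(262, 3, 1, 1)                          # Photometric: BlackIsZero
    wtag(273, 4, 1, data_off + (z - 1) * data_bytes) # StripOffsets
    wtag(277, 3, 1, 1)                          # SamplesPerPixel
    wtag(278, 4, 1, ny)                         # RowsPerStrip
    wtag(279, 4, 1, data_bytes)                 # StripByteCounts
    wtag(339, 3, 1, 3)                          # SampleFormat: IEEE float
    next_ifd <- if (z < nz) ifd0_off + z * ifd_size else 0
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed grayscale TIFF z-stack
#'
#' Supports the subset written by [write_tiff()]: little-endian,
#' uncompressed, single-sample 32-bit float or 8/16-bit unsigned integer
#' pages of equal size.
#'
#' @param path TIFF path.
#' @return 3D array (z, y, x).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) {
    as.numeric(as.integer(raw[off + 1])) + 256 * as.integer(raw[off + 2]) +
      65536 * as.integer(raw[off + 3]) + 16777216 * as.integer(raw[off + 4])
  }
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF")
  ifd <- u32(4)
  slices <- list()
  while (ifd != 0) {
    nt <- u16(ifd)
    tags <- list()
    for (k in seq_len(nt)) {
      off <- ifd + 2 + (k - 1) * 12
      id <- u16(off); type <- u16(off + 2)
      val <- if (type == 3) u16(off + 8) else u32(off + 8)
      tags[[as.character(id)]] <- val
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    if ((g(259, 1)) != 1) stop("compressed TIFF not supported")
    nx <- g(256); ny <- g(257); bits <- g(258, 1)
    fmt <- g(339, 1)
    strip_off <- g(273); n_bytes <- g(279)
    bytes_px <- bits / 8
    if (is.null(nx) || is.null(ny) || is.null(strip_off))
      stop("missing required TIFF tags")
    vals <- if (fmt == 3 && bits == 32) {
      readBin(raw[(strip_off + 1):(strip_off + n_bytes)], "numeric",
              n = nx * ny, size = 4, endian = "little")
    } else if (fmt == 1 && bits %in% c(8, 16)) {
      readBin(raw[(strip_off + 1):(strip_off + n_bytes)], "integer",
              n = nx * ny, size = bytes_px, signed = FALSE,
              endian = "little")
    } else stop("unsupported TIFF sample format")
    slices[[length(slices) + 1L]] <- t(matrix(vals, nrow = nx, ncol = ny))
    ifd <- u32(ifd + 2 + nt * 12)
  }
  nz <- length(slices)
  out <- array(0, dim = c(nz, nrow(slices[[1]]), ncol(slices[[1]])))
  for (z in seq_len(nz)) out[z, , ] <- slices[[z]]
  out
}
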