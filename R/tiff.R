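# Minimal uncompressed grayscale TIFF I/O.
#
# The analysis environment has no TIFF package, so the package carries its
# own reader/writer for the narrow slice of the format it needs: baseline
# TIFF, little- or big-endian, uncompressed, single-sample grayscale pages
# (uint8/uint16/float32), multi-page via the IFD chain. Pages are stored
# row-major (top row first); in R each page is a ny x nx matrix.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)

#' Write matrices as a multi-page grayscale TIFF
#'
#' @param pages a matrix or list of numeric matrices (all same dimensions).
#' @param path output file path.
#' @param bits 8, 16 (unsigned integer) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_tiff_pages <- function(pages, path, bits = 32) {
  if (is.matrix(pages)) pages <- list(pages)
  assert_that(length(pages) >= 1, "no pages to write")
  assert_that(bits %in% c(8, 16, 32), "bits must be 8, 16 or 32")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  for (p in pages)
    assert_that(is.matrix(p) && nrow(p) == ny && ncol(p) == nx,
                "inconsistent page shapes")
  bpp <- bits / 8
  strip_bytes <- ny * nx * bpp
  n_entries <- 10L
  ifd_bytes <- 2L + n_entries * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  # header: II, 42, offset of first IFD (first strip follows header)
  writeBin(charToRaw("II"), con)
  wb(42L, 2)
  first_ifd <- 8L + strip_bytes
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")

  offset <- 8L
  for (i in seq_along(pages)) {
    dat <- as.vector(t(pages[[i]]))  # row-major
    if (bits == 32) {
      writeBin(as.numeric(dat), con, size = 4, endian = "little")
    } else {
      maxv <- 2^bits - 1
      writeBin(as.integer(pmin(pmax(round(dat), 0), maxv)), con,
               size = bpp, endian = "little")
    }
    strip_off <- offset
    ifd_off <- strip_off + strip_bytes
    # IFD entries must be ascending by tag id
    entry <- function(tag, type, count, value) {
      wb(tag, 2); wb(type, 2)
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3) { wb(value, 2); wb(0L, 2) }  # SHORT padded
      else writeBin(as.integer(value), con, size = 4, endian = "little")
    }
    wb(n_entries, 2)
    entry(256, 4, 1, nx)                       # ImageWidth
    entry(257, 4, 1, ny)                       # ImageLength
    entry(258, 3, 1, bits)                     # BitsPerSample
    entry(259, 3, 1, 1)                        # Compression: none
    entry(262, 3, 1, 1)                        # Photometric: BlackIsZero
    entry(273, 4, 1, strip_off)                # StripOffsets
    entry(277, 3, 1, 1)                        # SamplesPerPixel
    entry(278, 4, 1, ny)                       # RowsPerStrip
    entry(279, 4, 1, strip_bytes)              # StripByteCounts
    entry(339, 3, 1, if (bits == 32) 3 else 1) # SampleFormat
    # the next page's strip follows this IFD; its IFD comes after that strip
    next_ifd <- if (i < length(pages)) ifd_off + ifd_bytes + strip_bytes else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    offset <- ifd_off + ifd_bytes
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports uncompressed single-sample pages with 8/16-bit unsigned or
#' 32-bit float samples, either byte order, and multiple strips per page.
#'
#' @param path TIFF file path.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff_pages <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop_mf("not a TIFF file: ", path)
  rd_int <- function(off, size, n = 1) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size == 4)
  }
  magic <- rd_int(2, 2)
  assert_that(magic == 42, "bad TIFF magic number")
  ifd_off <- rd_int(4, 4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- rd_int(ifd_off, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- rd_int(base, 2); type <- rd_int(base + 2, 2)
      count <- rd_int(base + 4, 4)
      tsz <- TIFF_TYPE_SIZES[type]
      nbytes <- tsz * count
      voff <- if (nbytes <= 4) base + 8 else rd_int(base + 8, 4)
      vals <- if (type %in% c(3, 4, 1))
        rd_int(voff, tsz, count) else NA
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    nx <- g(256); ny <- g(257)
    bits <- g(258, 1); comp <- g(259, 1); fmt <- g(339, 1)
    spp <- g(277, 1)
    assert_that(!is.null(nx) && !is.null(ny), "missing image dimensions")
    assert_that(comp == 1, "only uncompressed TIFF supported (compression=", comp, ")")
    assert_that(spp == 1, "only single-sample grayscale supported")
    offs <- g(273); cnts <- g(279)
    dat <- numeric(0)
    bpp <- bits / 8
    for (s in seq_along(offs)) {
      seg <- raw[(offs[s] + 1):(offs[s] + cnts[s])]
      vals <- if (fmt == 3 && bits == 32)
        readBin(seg, "numeric", n = cnts[s] / 4, size = 4, endian = endian)
      else if (bits == 8)
        as.numeric(readBin(seg, "integer", n = cnts[s], size = 1,
                           signed = FALSE, endian = endian))
      else if (bits == 16)
        as.numeric(readBin(seg, "integer", n = cnts[s] / 2, size = 2,
                           signed = FALSE, endian = endian))
      else stop_mf("unsupported sample layout: ", bits, " bits, format ", fmt)
      dat <- c(dat, vals)
    }
    assert_that(length(dat) == nx * ny, "strip data does not match page size")
    pages[[length(pages) + 1]] <- matrix(dat, nrow = ny, ncol = nx, byrow = TRUE)
    ifd_off <- rd_int(ifd_off + 2 + n_entries * 12, 4)
  }
  pages
}
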