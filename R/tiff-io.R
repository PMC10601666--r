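# Minimal multi-page TIFF codec: uncompressed, little-endian, single-sample
# grayscale. Supports unsigned 8/16/32-bit integer and 32-bit float pages.
# Exists because no TIFF-capable package ships with the target image; scope is
# exactly what the atlas masks and rendered sections need.

TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples_per_pixel = 277L,
  rows_per_strip = 278L, strip_byte_counts = 279L, sample_format = 339L
)

#' Write a stack of matrices as a multi-page TIFF
#'
#' Pages are written uncompressed, little-endian, one strip per page.
#' Integer data are stored as unsigned 8/16/32-bit (smallest width that
#' holds the range unless `bits` is given); numeric data with a fractional
#' part are stored as 32-bit IEEE floats.
#'
#' @param pages a matrix or list of matrices (rows = image rows).
#' @param path output file path.
#' @param bits storage bit depth for integer data: 8, 16 or 32. Ignored for
#'   float pages.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(pages, path, bits = 16L) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1))))
  if (!bits %in% c(8L, 16L, 32L)) stop("bits must be 8, 16 or 32")

  con <- file(path, "wb")
  on.exit(close(con))
  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  writeChar("II", con, nchars = 2, eos = NULL)
  w_u16(42L)
  w_u32(8L)  # first IFD directly after header: patched below per page

  # Layout: header(8) | page1 data | page1 IFD | page2 data | page2 IFD ...
  # We must know offsets up front, so compute sizes first.
  n <- length(pages)
  page_info <- lapply(pages, function(m) {
    is_float <- is.double(m) && any(abs(m - round(m)) > 1e-9, na.rm = TRUE)
    if (any(!is.finite(m))) stop("non-finite pixel values")
    if (is_float) {
      list(float = TRUE, bits = 32L, bytes = 4L * length(m))
    } else {
      if (any(m < 0)) stop("negative pixel values not representable (unsigned TIFF)")
      if (max(m, 0) >= 2^bits) stop("pixel values exceed ", bits, "-bit range")
      list(float = FALSE, bits = as.integer(bits), bytes = bits %/% 8L * length(m))
    }
  })

  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  offset <- 8L
  data_off <- integer(n); ifd_off <- integer(n)
  for (i in seq_len(n)) {
    data_off[i] <- offset
    ifd_off[i] <- offset + page_info[[i]]$bytes
    offset <- ifd_off[i] + ifd_size
  }
  # patch first-IFD pointer
  seek(con, 4L, rw = "write"); w_u32(ifd_off[1])

  tag <- function(id, type, count, value) {
    w_u16(id); w_u16(type); w_u32(count)
    if (type == 3L && count == 1L) { w_u16(value); w_u16(0L) } else w_u32(value)
  }

  for (i in seq_len(n)) {
    m <- pages[[i]]
    info <- page_info[[i]]
    seek(con, data_off[i], rw = "write")
    v <- as.vector(t(m))  # TIFF strips are row-major
    if (info$float) {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      sz <- info$bits %/% 8L
      if (info$bits == 32L) {
        # writeBin size=4 signed covers < 2^31; values >= 2^31 unsupported
        if (max(v, 0) >= 2^31) stop("uint32 values >= 2^31 unsupported")
        writeBin(as.integer(v), con, size = 4, endian = "little")
      } else {
        writeBin(as.integer(v), con, size = sz, endian = "little")
      }
    }
    seek(con, ifd_off[i], rw = "write")
    w_u16(n_tags)
    tg <- TIFF_TAGS
    tag(tg[["width"]], 3L, 1L, ncol(m))
    tag(tg[["length"]], 3L, 1L, nrow(m))
    tag(tg[["bits"]], 3L, 1L, info$bits)
    tag(tg[["compression"]], 3L, 1L, 1L)
    tag(tg[["photometric"]], 3L, 1L, 1L)
    tag(tg[["strip_offsets"]], 4L, 1L, data_off[i])
    tag(tg[["samples_per_pixel"]], 3L, 1L, 1L)
    tag(tg[["rows_per_strip"]], 3L, 1L, nrow(m))
    tag(tg[["strip_byte_counts"]], 4L, 1L, info$bytes)
    tag(tg[["sample_format"]], 3L, 1L, if (info$float) 3L else 1L)
    w_u32(if (i < n) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' Read a multi-page TIFF into a list of matrices
#'
#' Understands the subset written by [write_tiff_stack()] plus striped
#' baseline files from other writers: uncompressed, little- or big-endian,
#' one sample per pixel, uint 8/16/32 or float32.
#'
#' @param path TIFF file path.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop("not a TIFF file: ", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) v + 2^32 else v
  }
  if (u16(2) != 42) stop("bad TIFF magic in ", path)

  pages <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    n_tags <- u16(ifd)
    tags <- list()
    for (k in seq_len(n_tags)) {
      off <- ifd + 2 + (k - 1) * 12
      id <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      val_off <- off + 8
      unit <- c(`1` = 1, `3` = 2, `4` = 4)[as.character(type)]
      if (is.na(unit)) { tags[[as.character(id)]] <- NA; next }
      if (unit * count > 4) val_off <- u32(off + 8)
      vals <- vapply(seq_len(count), function(j) {
        o <- val_off + (j - 1) * unit
        if (unit == 2) u16(o) else if (unit == 4) u32(o)
        else as.integer(raw[o + 1])
      }, numeric(1))
      tags[[as.character(id)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    width <- g(256); height <- g(257)
    bits <- g(258, 8); comp <- g(259, 1); fmt <- g(339, 1)
    spp <- g(277, 1)
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    if (comp != 1) stop("unsupported TIFF compression: ", comp)
    if (spp != 1) stop("only single-sample TIFF supported")
    if (!(fmt %in% c(1, 3))) stop("unsupported TIFF sample format: ", fmt)
    if (fmt == 3 && bits != 32) stop("only 32-bit float TIFF supported")
    if (fmt == 1 && !bits %in% c(8, 16, 32)) stop("unsupported bit depth: ", bits)

    offs <- g(273); cnts <- g(279)
    bytes <- do.call(c, lapply(seq_along(offs), function(s) {
      raw[(offs[s] + 1):(offs[s] + cnts[s])]
    }))
    npx <- width * height
    v <- if (fmt == 3) {
      readBin(bytes, "numeric", n = npx, size = 4, endian = endian)
    } else if (bits == 32) {
      x <- readBin(bytes, "integer", n = npx, size = 4, endian = endian)
      ifelse(x < 0, x + 2^32, as.numeric(x))
    } else {
      as.numeric(readBin(bytes, "integer", n = npx, size = bits %/% 8,
                         signed = FALSE, endian = endian))
    }
    pages[[length(pages) + 1]] <- matrix(v, nrow = height, ncol = width,
                                         byrow = TRUE)
    ifd <- u32(ifd + 2 + n_tags * 12)
  }
  pages
}
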