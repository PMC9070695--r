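## Stack I/O. Internal axis order is always (angle, h, v); computation is in
## 64-bit floats, files are 32-bit. TIFF support is a minimal self-contained
## dialect (little-endian, uncompressed, one 32-bit float strip per page,
## one page per angle) because no TIFF binding is available; it round-trips
## exactly in 32-bit precision and is readable by standard TIFF tools.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_bytes = 279L, sample_format = 339L)

#' Write a projection stack as a multi-page 32-bit float TIFF
#'
#' One page per angle; page rows are the horizontal displacement axis,
#' columns the vertical. Values are stored as little-endian IEEE floats,
#' uncompressed.
#'
#' @param stack 3-D array `(angle, h, v)`.
#' @param path output file path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  d <- dim(stack)
  m0 <- d[1]; m1 <- d[2]; m2 <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  page_bytes <- 4L * m1 * m2
  n_entries <- 9L
  ifd_size <- 2L + 12L * n_entries + 4L
  # layout: 8-byte header, all pixel data, then the IFD chain
  data_start <- 8L
  ifd_start <- data_start + m0 * page_bytes
  writeBin(charToRaw("II"), con)
  writeBin(c(42L), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_start), con, size = 4, endian = "little")
  for (a in seq_len(m0)) {
    # row-major page: rows = h, cols = v
    writeBin(as.vector(t(matrix(stack[a, , ], m1, m2))), con,
             size = 4, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (a in seq_len(m0)) {
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256, 4, 1, m2)                      # width = v extent
    entry(257, 4, 1, m1)                      # length (rows) = h extent
    entry(258, 3, 1, 32)                      # bits per sample
    entry(259, 3, 1, 1)                       # no compression
    entry(262, 3, 1, 1)                       # black is zero
    entry(273, 4, 1, data_start + (a - 1L) * page_bytes)
    entry(278, 4, 1, m1)                      # rows per strip
    entry(279, 4, 1, page_bytes)
    entry(339, 3, 1, 3)                       # IEEE float
    nxt <- if (a < m0) ifd_start + a * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Reads the uncompressed single-strip dialect written by [write_stack()]
#' (32-bit float or 16-bit unsigned samples). The axis order of the result
#' is always `(angle, h, v)`; `axis_order` declares how the file's
#' `(page, row, col)` axes map onto `(angle, h, v)`.
#'
#' @param path file path.
#' @param axis_order character permutation of `c("angle", "h", "v")` giving
#'   the meaning of `(page, row, col)` (default identity).
#' @return 3-D numeric array `(angle, h, v)`.
#' @export
read_stack <- function(path, axis_order = c("angle", "h", "v")) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(setequal(axis_order, c("angle", "h", "v")))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42) {
    stop("not a little-endian TIFF: ", path)
  }
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u16(off); type <- u16(off + 2)
      val <- if (type == 3) u16(off + 8) else u32(off + 8)
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) {
        if (is.null(default)) stop("missing TIFF tag ", t)
        default
      } else v
    }
    if (g(259, 1) != 1) stop("compressed TIFF not supported")
    w <- g(256); h <- g(257)
    bits <- g(258, 8); fmt <- g(339, 1)
    so <- g(273); sb <- g(279, w * h * bits / 8)
    pages[[length(pages) + 1]] <- list(w = w, h = h, bits = bits, fmt = fmt,
                                       offset = so, bytes = sb)
    ifd <- u32(ifd + 2 + n * 12)
  }
  if (length(pages) == 0) stop("empty TIFF: ", path)
  w <- pages[[1]]$w; h <- pages[[1]]$h
  vol <- array(0, dim = c(length(pages), h, w))
  for (a in seq_along(pages)) {
    p <- pages[[a]]
    if (p$w != w || p$h != h) stop("inconsistent page shapes in ", path)
    bytes <- raw[(p$offset + 1):(p$offset + p$bytes)]
    vals <- if (p$fmt == 3 && p$bits == 32) {
      readBin(bytes, "double", n = p$w * p$h, size = 4, endian = "little")
    } else if (p$fmt %in% c(1, 4) && p$bits == 16) {
      readBin(bytes, "integer", n = p$w * p$h, size = 2, signed = FALSE,
              endian = "little")
    } else {
      stop("unsupported sample format (fmt=", p$fmt, ", bits=", p$bits, ")")
    }
    vol[a, , ] <- t(matrix(vals, p$w, p$h))  # stored row-major
  }
  perm <- match(c("angle", "h", "v"), axis_order)
  if (!all(perm == 1:3)) vol <- aperm(vol, perm)
  vol
}

#' Read a single 2-D field image (first page of a TIFF)
#' @param path file path.
#' @return 2-D matrix `(h, v)`.
#' @export
read_field <- function(path) {
  v <- read_stack(path)
  matrix(v[1, , ], dim(v)[2], dim(v)[3])
}
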