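# Minimal baseline TIFF codec (uncompressed, single-sample greyscale,
# multi-page, little-endian). The offline R stack ships no TIFF package,
# so the package carries its own reader/writer for the subset it needs:
# 8/16-bit unsigned and 32/64-bit float pages, one strip per page, plus an
# ImageDescription tag holding JSON metadata on the first page. Anything
# fancier (compression, tiles, palettes) is rejected with a clear error.

.tiff_types <- list(uint8 = list(bits = 8L, fmt = 1L, size = 1L),
                    uint16 = list(bits = 16L, fmt = 1L, size = 2L),
                    float32 = list(bits = 32L, fmt = 3L, size = 4L),
                    float64 = list(bits = 64L, fmt = 3L, size = 8L))

#' Write a multi-page greyscale TIFF
#'
#' @param pages A list of numeric matrices (all the same size), or a single
#'   matrix; each matrix becomes one page (row = Y, column = X).
#' @param path Output file.
#' @param dtype Pixel storage type: `"uint8"`, `"uint16"`, `"float32"`
#'   (default) or `"float64"` (lossless for R doubles).
#' @param description Optional character scalar stored in the first page's
#'   ImageDescription tag (used for JSON metadata sidecars).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, dtype = "float32", description = NULL) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, dtype %in% names(.tiff_types))
  tt <- .tiff_types[[dtype]]
  ny <- nrow(pages[[1L]])
  nx <- ncol(pages[[1L]])
  for (p in pages)
    if (nrow(p) != ny || ncol(p) != nx)
      stop("write_tiff: all pages must share one shape")
  desc <- NULL
  if (!is.null(description)) {
    desc <- c(charToRaw(as.character(description)), as.raw(0L))
    if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0L))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry <- function(tag, type, count, value) {
    wr2(tag); wr2(type); wr4(count)
    if (type == 3L) { wr2(value); wr2(0L) } else wr4(value)
  }
  writeBin(charToRaw("II"), con)
  wr2(42L)
  wr4(8L)                                   # first IFD right after header
  data_bytes <- as.numeric(ny) * nx * tt$size
  if (data_bytes > .Machine$integer.max / 2)
    stop("write_tiff: page too large for this writer")
  offset <- 8
  n_pages <- length(pages)
  for (k in seq_len(n_pages)) {
    has_desc <- !is.null(desc) && k == 1L
    n_entries <- 9L + as.integer(has_desc)
    ifd_size <- 2 + n_entries * 12 + 4
    desc_len <- if (has_desc) length(desc) else 0
    desc_off <- offset + ifd_size
    data_off <- desc_off + desc_len
    next_off <- if (k < n_pages) data_off + data_bytes else 0
    wr2(n_entries)
    entry(256L, 3L, 1L, nx)                 # ImageWidth
    entry(257L, 3L, 1L, ny)                 # ImageLength
    entry(258L, 3L, 1L, tt$bits)            # BitsPerSample
    entry(259L, 3L, 1L, 1L)                 # Compression = none
    entry(262L, 3L, 1L, 1L)                 # Photometric = BlackIsZero
    if (has_desc) entry(270L, 2L, length(desc), desc_off)
    entry(273L, 4L, 1L, data_off)           # StripOffsets
    entry(278L, 3L, 1L, ny)                 # RowsPerStrip
    entry(279L, 4L, 1L, data_bytes)         # StripByteCounts
    entry(339L, 3L, 1L, tt$fmt)             # SampleFormat
    wr4(next_off)
    if (has_desc) writeBin(desc, con)
    v <- as.vector(t(pages[[k]]))           # row-major on disk
    if (tt$fmt == 1L) {
      v <- round(v)
      if (dtype == "uint8") writeBin(as.raw(pmin(pmax(v, 0), 255)), con)
      else {
        v <- pmin(pmax(v, 0), 65535)
        v <- ifelse(v > 32767, v - 65536, v)  # two's-complement bit pattern
        writeBin(as.integer(v), con, size = 2L, endian = "little")
      }
    } else {
      writeBin(as.numeric(v), con, size = tt$size, endian = "little")
    }
    offset <- offset + ifd_size + desc_len + data_bytes
  }
  invisible(path)
}

#' Read a multi-page greyscale TIFF
#'
#' Reads uncompressed single-sample TIFFs (both byte orders) as written by
#' [write_tiff()] or any writer using baseline greyscale encoding.
#'
#' @param path TIFF file.
#' @return A list of numeric matrices with attribute `description` (the
#'   first page's ImageDescription, or `NULL`).
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8L) stop("read_tiff: '", path, "' is not a TIFF")
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
    else stop("read_tiff: '", path, "' is not a TIFF (bad byte order mark)")
  rd <- function(off, n, size, signed = TRUE)
    readBin(raw_all[(off + 1):(off + n * size)], "integer", n = n,
            size = size, signed = signed, endian = endian)
  if (rd(2, 1, 2, signed = FALSE) != 42L)
    stop("read_tiff: '", path, "' is not a TIFF (bad magic)")
  ifd_off <- rd(4, 1, 4)
  pages <- list()
  description <- NULL
  while (ifd_off > 0) {
    n_entries <- rd(ifd_off, 1, 2, signed = FALSE)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eo <- ifd_off + 2 + (e - 1) * 12
      tag <- rd(eo, 1, 2, signed = FALSE)
      type <- rd(eo + 2, 1, 2, signed = FALSE)
      count <- rd(eo + 4, 1, 4)
      type_size <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
      if (is.na(type_size)) { tags[[as.character(tag)]] <- NULL; next }
      inline <- count * type_size <= 4
      voff <- if (inline) eo + 8 else rd(eo + 8, 1, 4)
      val <- if (type == 2L) {
        rawToChar(raw_all[(voff + 1):(voff + count - 1)])
      } else rd(voff, count, type_size, signed = type_size == 4L)
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("read_tiff: missing required tag ", tag)
        default
      } else v
    }
    nx <- need(256L)
    ny <- need(257L)
    bits <- need(258L, 1L)
    if (need(259L, 1L) != 1L)
      stop("read_tiff: compressed TIFFs are not supported")
    if (need(277L, 1L) != 1L)
      stop("read_tiff: only single-sample greyscale TIFFs are supported")
    fmt <- need(339L, 1L)
    offs <- need(273L)
    cnts <- need(279L)
    if (!is.null(tags[["270"]]) && is.null(description))
      description <- tags[["270"]]
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw_all[(offs[s] + 1):(offs[s] + cnts[s])])
    v <- if (fmt == 3L) {
      readBin(buf, "double", n = nx * ny, size = bits / 8L, endian = endian)
    } else if (bits == 8L) {
      as.integer(readBin(buf, "integer", n = nx * ny, size = 1L,
                         signed = FALSE, endian = endian))
    } else if (bits == 16L) {
      readBin(buf, "integer", n = nx * ny, size = 2L, signed = FALSE,
              endian = endian)
    } else stop("read_tiff: unsupported integer bit depth ", bits)
    pages[[length(pages) + 1L]] <- matrix(as.numeric(v), ny, nx, byrow = TRUE)
    ifd_off <- rd(ifd_off + 2 + n_entries * 12, 1, 4)
  }
  attr(pages, "description") <- description
  pages
}
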