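# Minimal baseline TIFF codec.
#
# The analysis exchanges images as plain uncompressed grayscale TIFF
# (single- or multi-page, uint8/uint16/float32, strip layout). Nothing in
# the supported R stack provides TIFF I/O, so the small baseline subset is
# implemented here directly; it round-trips exactly and reads files written
# by the common scientific writers (tifffile, Fiji "raw" save) as long as
# they are uncompressed single-sample grayscale.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

#' Write matrices as an uncompressed grayscale TIFF
#'
#' @param x a numeric matrix, a list of equally-shaped matrices (pages), an
#'   [image2d] or an [image_stack].
#' @param path output file.
#' @param dtype `"auto"` (uint16 when all values are integers in
#'   `[0, 65535]`, else float32), `"uint8"`, `"uint16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, dtype = c("auto", "uint8", "uint16", "float32")) {
  dtype <- match.arg(dtype)
  if (inherits(x, "image2d")) x <- x$intensity
  if (inherits(x, "image_stack")) x <- x$frames
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x) || !all(vapply(x, is.matrix, logical(1))))
    stop("x must be a matrix or list of matrices")
  vals <- unlist(lapply(x, range))
  if (dtype == "auto") {
    all_int <- all(vapply(x, function(m) all(m == floor(m)), logical(1)))
    dtype <- if (all_int && min(vals) >= 0 && max(vals) <= 65535) "uint16" else "float32"
  }
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- if (dtype == "float32") 3L else 1L
  bytes_px <- bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  w16(42L)
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  H <- nrow(x[[1]]); W <- ncol(x[[1]])
  data_size <- H * W * bytes_px
  first_data <- 8L
  w32(first_data + data_size) # offset of first IFD
  tag <- function(id, type, value) { # single inline value
    w16(id); w16(type); w32(1L)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  off <- first_data
  for (i in seq_along(x)) {
    m <- x[[i]]
    if (nrow(m) != H || ncol(m) != W) stop("all pages must share the same shape")
    v <- as.vector(t(m)) # TIFF is row-major
    if (dtype == "float32") {
      writeBin(as.double(v), con, size = 4, endian = "little")
    } else {
      top <- 2^bits
      if (any(v < 0 | v >= top | v != floor(v)))
        stop(sprintf("values out of range for %s", dtype))
      v <- as.integer(ifelse(v >= top / 2, v - top, v)) # two's complement
      writeBin(v, con, size = bytes_px, endian = "little")
    }
    ifd_off <- off + data_size
    # IFD
    w16(n_tags)
    tag(256L, 4L, W)           # ImageWidth
    tag(257L, 4L, H)           # ImageLength
    tag(258L, 3L, bits)        # BitsPerSample
    tag(259L, 3L, 1L)          # Compression: none
    tag(262L, 3L, 1L)          # Photometric: BlackIsZero
    tag(273L, 4L, off)         # StripOffsets
    tag(277L, 3L, 1L)          # SamplesPerPixel
    tag(278L, 4L, H)           # RowsPerStrip
    tag(279L, 4L, data_size)   # StripByteCounts
    tag(339L, 3L, fmt)         # SampleFormat
    nxt <- if (i < length(x)) ifd_off + ifd_size + data_size else 0L
    w32(nxt)
    off <- ifd_off + ifd_size
  }
  invisible(path)
}

#' Read an uncompressed grayscale TIFF
#'
#' Supports the baseline subset written by [write_tiff()]: uncompressed,
#' single sample per pixel, 8/16/32-bit unsigned integer or 32-bit float,
#' one or more strips, little- or big-endian, multi-page.
#'
#' @param path TIFF file.
#' @param simplify return a bare matrix when the file has a single page.
#' @return A list of matrices (or a matrix when `simplify` and one page).
#' @export
read_tiff <- function(path, simplify = TRUE) {
  raw <- readBin(path, "raw", file.info(path)$size)
  order <- rawToChar(raw[1:2])
  en <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file")
  rd <- function(off, n, size, what = "integer", signed = TRUE)
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = en, signed = signed)
  u32 <- function(off, n = 1) {
    v <- rd(off, n, 4)
    ifelse(v < 0, v + 2^32, v)
  }
  u16 <- function(off, n = 1) rd(off, n, 2, signed = FALSE)
  if (u16(2) != 42) stop("bad TIFF magic")
  ifd_off <- u32(4)
  pages <- list()
  while (ifd_off != 0) {
    n_tags <- u16(ifd_off)
    tags <- list()
    for (k in seq_len(n_tags)) {
      e <- ifd_off + 2 + (k - 1) * 12
      id <- u16(e); type <- u16(e + 2); cnt <- u32(e + 4)
      sz <- TIFF_TYPE_SIZE[[as.character(type)]]
      voff <- if (cnt * sz <= 4) e + 8 else u32(e + 8)
      val <- switch(as.character(type),
                    `3` = u16(voff, cnt),
                    `4` = u32(voff, cnt),
                    `1` = rd(voff, cnt, 1, signed = FALSE),
                    u32(voff, min(cnt, 1)))
      tags[[as.character(id)]] <- val
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    W <- g(256); H <- g(257)
    bits <- g(258, 1L)[1]
    if (g(259, 1L) != 1) stop("compressed TIFF not supported")
    if (g(277, 1L) != 1) stop("only single-sample grayscale TIFF supported")
    fmt <- g(339, 1L)[1]
    offs <- g(273); counts <- g(279)
    buf <- raw[unlist(mapply(function(o, n) (o + 1):(o + n), offs, counts,
                             SIMPLIFY = FALSE))]
    n_px <- H * W
    v <- if (fmt == 3) {
      readBin(buf, "double", n = n_px, size = 4, endian = en)
    } else if (bits == 32) {
      x <- readBin(buf, "integer", n = n_px, size = 4, endian = en)
      ifelse(x < 0, x + 2^32, x)
    } else {
      readBin(buf, "integer", n = n_px, size = bits / 8, endian = en,
              signed = FALSE)
    }
    pages[[length(pages) + 1]] <- matrix(v, nrow = H, ncol = W, byrow = TRUE)
    ifd_off <- u32(ifd_off + 2 + n_tags * 12)
  }
  if (simplify && length(pages) == 1) pages[[1]] else pages
}

#' Read a cell ROI polygon from JSON
#'
#' Expected format: `{"polygon": [[row, col], ...]}` with 0-based pixel
#' coordinates.
#'
#' @param path JSON file.
#' @return A [cell_roi].
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$polygon)) stop("ROI JSON must contain a 'polygon' field")
  cell_roi(matrix(as.numeric(obj$polygon), ncol = 2))
}

#' Write a cell ROI polygon to JSON
#'
#' @param roi a [cell_roi].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "cell_roi"))
  jsonlite::write_json(list(polygon = roi$polygon), path, digits = NA)
  invisible(path)
}

# deterministic CSV writer (fixed na/quote/eol so identical inputs give
# byte-identical files; pipeline determinism is asserted on these bytes)
write_csv_strict <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA",
                   eol = "\n")
  invisible(path)
}
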