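# Minimal baseline-TIFF codec (little-endian, uncompressed, single-sample
# grayscale, one strip per page). No R TIFF package is available in the
# target environment, so the subset of TIFF 6.0 the pipeline needs is
# implemented here: 16-bit unsigned pages for movies/labels and 32-bit
# IEEE float pages for maps. Cross-validated against Python tifffile in
# the test suite.

.tiff_tags <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
                Compression = 259L, Photometric = 262L, StripOffsets = 273L,
                RowsPerStrip = 278L, StripByteCounts = 279L,
                SampleFormat = 339L)

.pack_u16 <- function(v) {
  v <- as.integer(round(v))
  r <- raw(2L * length(v))
  r[c(TRUE, FALSE)] <- as.raw(v %% 256L)
  r[c(FALSE, TRUE)] <- as.raw(v %/% 256L)
  r
}

.pack_u32 <- function(v) {
  v <- as.numeric(v)
  r <- raw(4L * length(v))
  r[seq(1L, length(r), 4L)] <- as.raw(v %% 256)
  r[seq(2L, length(r), 4L)] <- as.raw((v %/% 256) %% 256)
  r[seq(3L, length(r), 4L)] <- as.raw((v %/% 65536) %% 256)
  r[seq(4L, length(r), 4L)] <- as.raw(v %/% 16777216)
  r
}

.unpack_u16 <- function(r) {
  as.integer(r[c(TRUE, FALSE)]) + 256L * as.integer(r[c(FALSE, TRUE)])
}

.unpack_u32 <- function(r) {
  i <- as.integer(r)
  i[seq(1L, length(i), 4L)] + 256 * i[seq(2L, length(i), 4L)] +
    65536 * i[seq(3L, length(i), 4L)] + 16777216 * i[seq(4L, length(i), 4L)]
}

# one 12-byte IFD entry; type 3 = SHORT, 4 = LONG, value inline
.ifd_entry <- function(tag, type, value) {
  c(.pack_u16(tag), .pack_u16(type),
    .pack_u32(1L),
    if (type == 3L) c(.pack_u16(value), .pack_u16(0L)) else .pack_u32(value))
}

#' Write a grayscale multi-page TIFF
#'
#' Writes an H x W x T array (or H x W matrix) as an uncompressed
#' little-endian TIFF, one page per T slice, one strip per page.
#'
#' @param data Numeric array `H x W x T` or matrix `H x W`. For
#'   `"uint16"` values must be integers in `[0, 65535]`.
#' @param path Output path.
#' @param sample_format `"uint16"` or `"float32"`.
#' @export
tiff_write <- function(data, path, sample_format = c("uint16", "float32")) {
  sample_format <- match.arg(sample_format)
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L)
  h <- dim(data)[1]; w <- dim(data)[2]; np <- dim(data)[3]
  bps <- if (sample_format == "uint16") 16L else 32L
  bytes_px <- bps / 8L
  if (sample_format == "uint16" &&
      (any(data < 0) || any(data > 65535) || any(data != round(data)))) {
    stop("uint16 TIFF requires integer values in [0, 65535]")
  }
  strip_bytes <- h * w * bytes_px
  n_entries <- 9L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  page_bytes <- strip_bytes + ifd_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  # header: II, magic 42, offset of first IFD (follows first strip)
  writeBin(charToRaw("II"), con)
  writeBin(c(.pack_u16(42L), .pack_u32(8L + strip_bytes)), con)
  sf_code <- if (sample_format == "uint16") 1L else 3L
  for (p in seq_len(np)) {
    # pixel data, row-major (TIFF rows = image rows)
    page <- t(data[, , p])
    raw_px <- if (sample_format == "uint16") .pack_u16(as.vector(page))
              else writeBin(as.numeric(page), raw(), size = 4L,
                            endian = "little")
    strip_off <- 8L + (p - 1L) * page_bytes
    ifd_off <- strip_off + strip_bytes
    # next IFD sits after the NEXT page's strip
    next_ifd <- if (p < np) 8L + p * page_bytes + strip_bytes else 0L
    ifd <- c(.pack_u16(n_entries),
             .ifd_entry(256L, 4L, w),
             .ifd_entry(257L, 4L, h),
             .ifd_entry(258L, 3L, bps),
             .ifd_entry(259L, 3L, 1L),
             .ifd_entry(262L, 3L, 1L),
             .ifd_entry(273L, 4L, strip_off),
             .ifd_entry(278L, 4L, h),
             .ifd_entry(279L, 4L, strip_bytes),
             .ifd_entry(339L, 3L, sf_code),
             .pack_u32(next_ifd))
    writeBin(c(raw_px, ifd), con)
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF
#'
#' Reads the uncompressed little-endian grayscale subset written by
#' [tiff_write()] (also accepts multi-strip pages).
#'
#' @param path TIFF file path.
#' @return List with `data` (numeric `H x W x T` array) and
#'   `sample_format` (`"uint16"` or `"float32"`).
#' @export
tiff_read <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (rawToChar(raw_all[1:2]) != "II" || .unpack_u16(raw_all[3:4]) != 42L) {
    stop("not a little-endian TIFF file: ", path)
  }
  u32_at <- function(off) .unpack_u32(raw_all[(off + 1):(off + 4)])
  u16_at <- function(off) .unpack_u16(raw_all[(off + 1):(off + 2)])
  ifd_off <- u32_at(4L)
  pages <- list()
  sf_seen <- NULL
  while (ifd_off != 0L) {
    n <- u16_at(ifd_off)
    tags <- list()
    for (e in seq_len(n)) {
      eo <- ifd_off + 2L + (e - 1L) * 12L
      tag <- u16_at(eo); type <- u16_at(eo + 2L); count <- u32_at(eo + 4L)
      val <- if (count == 1L) {
        if (type == 3L) u16_at(eo + 8L) else u32_at(eo + 8L)
      } else {
        voff <- u32_at(eo + 8L)
        if (type == 3L) {
          vapply(seq_len(count), function(k) u16_at(voff + 2L * (k - 1L)),
                 numeric(1))
        } else {
          vapply(seq_len(count), function(k) u32_at(voff + 4L * (k - 1L)),
                 numeric(1))
        }
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) tags[[as.character(t)]] %||% default
    if (g(259L, 1L) != 1L) stop("compressed TIFF not supported")
    bps <- g(258L); sf <- g(339L, 1L)
    if (!(identical(bps + 0, 16) && sf == 1L) &&
        !(identical(bps + 0, 32) && sf == 3L)) {
      stop("only 16-bit unsigned or 32-bit float grayscale supported")
    }
    w <- g(256L); h <- g(257L)
    offs <- g(273L); cnts <- g(279L)
    px_raw <- do.call(c, lapply(seq_along(offs), function(k) {
      raw_all[(offs[k] + 1):(offs[k] + cnts[k])]
    }))
    vals <- if (sf == 1L) .unpack_u16(px_raw)
            else readBin(px_raw, "double", n = w * h, size = 4L,
                         endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    sf_seen <- sf
    ifd_off <- u32_at(ifd_off + 2L + n * 12L)
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, c(h, w, length(pages)))
  for (p in seq_along(pages)) arr[, , p] <- pages[[p]]
  list(data = arr,
       sample_format = if (sf_seen == 1L) "uint16" else "float32")
}
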