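# Movie containers and the 4x-temporal / 2x2-spatial binning step.
#
# Image conventions: pixel (1,1) is the top-left of the field, rows
# (y) increase downward, columns (x) increase rightward; arrays are
# H x W x T (row, column, frame).

#' Raw widefield movie
#'
#' A 12-bit camera movie in a 16-bit container: `H x W x T` integer array
#' with values in `[0, 4095]`, acquired at `frame_rate_hz` (30 fps for the
#' standard protocol), plus the acquisition/stimulus metadata sidecar.
#'
#' @param data Integer array `H x W x T`, values in `[0, 4095]`.
#' @param frame_rate_hz Acquisition frame rate, Hz.
#' @param meta Named list; typically contains `stimulus`
#'   ([stimulus_spec()]) and `screen` ([screen_geometry()]).
#' @return An object of class `raw_movie`.
#' @export
raw_movie <- function(data, frame_rate_hz = 30, meta = list()) {
  stopifnot(length(dim(data)) == 3L, frame_rate_hz > 0)
  if (min(data) < 0 || max(data) > 4095) {
    stop("raw movie values must lie in [0, 4095] (12-bit contract)")
  }
  structure(list(data = data, frame_rate_hz = frame_rate_hz, meta = meta),
            class = "raw_movie")
}

#' Binned widefield movie
#'
#' The product of [bin_movie()]: sums over 4 x 2 x 2 (t, y, x) blocks of a
#' 12-bit raw movie, so values fit 16 bits (16 x 4095 = 65520) and the
#' effective frame rate is a quarter of the acquisition rate.
#'
#' @param data Integer array `(H/2) x (W/2) x (T/4)`.
#' @param frame_rate_hz Effective frame rate after binning, Hz.
#' @param meta Metadata carried over from the raw movie.
#' @param bin_factors Named integer vector `c(t=, y=, x=)`.
#' @return An object of class `binned_movie`.
#' @export
binned_movie <- function(data, frame_rate_hz, meta = list(),
                         bin_factors = c(t = 4L, y = 2L, x = 2L)) {
  stopifnot(length(dim(data)) == 3L)
  if (min(data) < 0 || max(data) > 65535) {
    stop("binned movie values must lie in [0, 65535]")
  }
  structure(list(data = data, frame_rate_hz = frame_rate_hz, meta = meta,
                 bin_factors = bin_factors),
            class = "binned_movie")
}

#' @export
print.raw_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raw_movie> %d x %d px, %d frames @ %g fps\n",
              d[1], d[2], d[3], x$frame_rate_hz))
  invisible(x)
}

#' @export
print.binned_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binned_movie> %d x %d px, %d frames @ %g fps (bin %s)\n",
              d[1], d[2], d[3], x$frame_rate_hz,
              paste(x$bin_factors, collapse = "x")))
  invisible(x)
}

.sidecar_path <- function(movie_path) {
  sub("\\.tiff?$", ".json", movie_path, ignore.case = TRUE)
}

#' Write a raw movie as multi-page TIFF plus JSON sidecar
#'
#' @param movie A [raw_movie()].
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "raw_movie"))
  tiff_write(movie$data, path, sample_format = "uint16")
  extra <- movie$meta[setdiff(names(movie$meta), c("stimulus", "screen"))]
  write_sidecar(movie$meta$stimulus, movie$meta$screen,
                extra = c(list(frame_rate_hz = movie$frame_rate_hz,
                               n_frames = dim(movie$data)[3]), extra),
                path = .sidecar_path(path))
  invisible(path)
}

#' Read a raw movie from multi-page TIFF plus JSON sidecar
#'
#' Validates the 12-bit contract and that the sidecar frame count matches
#' the TIFF page count.
#'
#' @param path TIFF path (sidecar expected next to it as `.json`).
#' @return A [raw_movie()].
#' @export
read_movie <- function(path) {
  sc_path <- .sidecar_path(path)
  if (!file.exists(sc_path)) stop("missing sidecar: ", sc_path)
  meta <- read_sidecar(sc_path)
  tif <- tiff_read(path)
  n_frames <- dim(tif$data)[3]
  if (!is.null(meta$n_frames) && meta$n_frames != n_frames) {
    stop(sprintf("sidecar frame count (%d) != TIFF page count (%d)",
                 meta$n_frames, n_frames))
  }
  if (max(tif$data) > 4095) {
    stop("TIFF contains values > 4095: violates the 12-bit contract")
  }
  fr <- meta$frame_rate_hz %||% 30
  keep <- setdiff(names(meta), c("frame_rate_hz", "n_frames"))
  data <- tif$data
  storage.mode(data) <- "integer"
  raw_movie(data, frame_rate_hz = fr, meta = meta[keep])
}

#' Bin a raw movie 4x temporally and 2x2 spatially
#'
#' Each output value is the SUM of the 16 parent samples (4 consecutive
#' frames x 2 x 2 pixels), which is exactly how 12-bit data become 16-bit
#' data: 16 x 4095 = 65520 fits a 16-bit container with no overflow. Total
#' intensity is conserved for divisible shapes. Spatial dimensions must be
#' even; a temporal remainder (T not divisible by 4) is dropped with a
#' warning.
#'
#' @param raw A [raw_movie()].
#' @return A [binned_movie()] at a quarter of the acquisition frame rate.
#' @export
bin_movie <- function(raw) {
  stopifnot(inherits(raw, "raw_movie"))
  d <- dim(raw$data)
  h <- d[1]; w <- d[2]; tt <- d[3]
  if (h %% 2L != 0L || w %% 2L != 0L) {
    stop("spatial dimensions must be even for 2x2 binning")
  }
  t_use <- (tt %/% 4L) * 4L
  if (t_use == 0L) stop("movie shorter than one temporal bin")
  if (t_use < tt) {
    warning(sprintf("dropping %d trailing frame(s) not filling a temporal bin",
                    tt - t_use))
  }
  x <- raw$data
  if (t_use < tt) x <- x[, , seq_len(t_use), drop = FALSE]
  # spatial 2x2 sum
  x <- x[seq(1L, h, 2L), , , drop = FALSE] + x[seq(2L, h, 2L), , , drop = FALSE]
  x <- x[, seq(1L, w, 2L), , drop = FALSE] + x[, seq(2L, w, 2L), , drop = FALSE]
  # temporal 4x sum
  m <- matrix(x, ncol = t_use)
  i1 <- seq(1L, t_use, 4L)
  b <- m[, i1] + m[, i1 + 1L] + m[, i1 + 2L] + m[, i1 + 3L]
  out <- array(b, c(h %/% 2L, w %/% 2L, t_use %/% 4L))
  stopifnot(max(out) <= 65535)  # impossible for valid 12-bit input
  binned_movie(out, frame_rate_hz = raw$frame_rate_hz / 4,
               meta = raw$meta)
}
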