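#' @useDynLib demixscale, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is new
#' @importFrom stats fft quantile rnorm rpois runif rexp median cor sd
#' @importFrom utils head tail
NULL

#' Fluorescence movie container
#'
#' A `VideoStack` holds a fluorescence movie as an `H x W x T` array of
#' real-valued intensities (arbitrary units) together with its frame rate.
#' Pixels are addressed in (row, col) order; the flattened pixel index is
#' row-major and 0-based, `d = row * W + col`, so that a movie corresponds to
#' a `D x T` matrix with `D = H * W`.  Movies may contain negative values
#' (offset-subtracted cameras): non-negativity is a property of the model
#' factors, never of the data.
#'
#' @param data numeric array of dimension `c(H, W, T)` (all values finite).
#' @param rate frame rate in frames per second.
#' @return an object of class `VideoStack` with fields `data`, `H`, `W`,
#'   `T`, `rate`.
#' @export
video_stack <- function(data, rate = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-d array (H x W x T)")
  if (!all(is.finite(data)))
    stop("movie contains non-finite values")
  d <- dim(data)
  if (any(d < 1L)) stop("H, W and T must all be >= 1")
  structure(
    list(data = data, H = d[1L], W = d[2L], T = d[3L], rate = rate),
    class = "VideoStack")
}

#' @export
print.VideoStack <- function(x, ...) {
  cat(sprintf("VideoStack: %d x %d pixels, %d frames @ %g Hz\n",
              x$H, x$W, x$T, x$rate))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.VideoStack <- function(x) c(x$H, x$W, x$T)

#' Flatten a movie to a pixel-by-time matrix (and back)
#'
#' `flatten()` reshapes an `H x W x T` movie into the `D x T` matrix used by
#' the factorization, with the row-major pixel convention `d = row * W + col`
#' (0-based).  `unflatten()` is its exact inverse.
#'
#' @param stack a [video_stack()].
#' @return for `flatten`, a `D x T` numeric matrix.
#' @export
flatten <- function(stack) {
  stopifnot(inherits(stack, "VideoStack"))
  # aperm puts the within-frame order to (col fastest varying last) so that
  # column-major vectorization enumerates pixels row-major
  matrix(aperm(stack$data, c(2L, 1L, 3L)), nrow = stack$H * stack$W,
         ncol = stack$T)
}

#' @rdname flatten
#' @param mat `D x T` matrix with `D = H * W`.
#' @param H,W grid dimensions.
#' @param rate frame rate of the reconstructed stack.
#' @export
unflatten <- function(mat, H, W, rate = 1) {
  mat <- as.matrix(mat)
  if (nrow(mat) != H * W)
    stop(sprintf("D = %d does not equal H * W = %d", nrow(mat), H * W))
  arr <- aperm(array(mat, dim = c(W, H, ncol(mat))), c(2L, 1L, 3L))
  video_stack(arr, rate = rate)
}

#' Convert between (row, col) coordinates and flat pixel indices
#'
#' Row-major 0-based flat index `d = row * W + col`; both helpers use
#' 0-based pixel coordinates and return/accept 0-based indices.
#'
#' @param rc two-column matrix of (row, col) pixel coordinates, 0-based.
#' @param W grid width.
#' @return integer vector of flat indices (0-based).
#' @export
pixel_index <- function(rc, W) {
  rc <- matrix(as.integer(rc), ncol = 2L)
  rc[, 1L] * as.integer(W) + rc[, 2L]
}

#' @rdname pixel_index
#' @param d flat pixel indices, 0-based.
#' @export
pixel_coord <- function(d, W) {
  d <- as.integer(d)
  cbind(row = d %/% as.integer(W), col = d %% as.integer(W))
}

#' Load a fluorescence movie from disk
#'
#' Reads a grayscale multi-page TIFF or a raw binary file with a JSON
#' sidecar header into a [video_stack()].  Values are converted to double
#' precision without rescaling.  The raw format expects a header file at
#' `<path>.json` (or given via `header`) naming `H`, `W`, `T`, `rate`,
#' `dtype` (one of `"float32"`, `"float64"`, `"int16"`, `"uint16"`,
#' `"int32"`) and `endian` (`"little"` or `"big"`); frames are stored
#' consecutively, each frame row-major.
#'
#' @param path file path.
#' @param format one of `"tiff"`, `"raw"`; default guesses from the
#'   extension.
#' @param header path of the JSON sidecar for raw input.
#' @return a [video_stack()].
#' @export
load_video <- function(path, format = c("auto", "tiff", "raw"),
                       header = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
              else "raw"
  }
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1L]])
    if (length(d) != 2L)
      stop("multi-channel TIFF not supported; field: channels")
    arr <- array(0, dim = c(d[1L], d[2L], length(pages)))
    for (t in seq_along(pages)) {
      if (!identical(dim(pages[[t]]), d))
        stop("dimension mismatch: page ", t, " differs from page 1")
      arr[, , t] <- pages[[t]]
    }
    return(video_stack(arr, rate = 1))
  }
  # raw + sidecar
  if (is.null(header)) header <- paste0(path, ".json")
  if (!file.exists(header)) stop("sidecar header not found: ", header)
  h <- jsonlite::fromJSON(header)
  for (f in c("H", "W", "T", "dtype"))
    if (is.null(h[[f]])) stop("sidecar header missing field: ", f)
  dtype <- as.character(h$dtype)
  spec <- switch(dtype,
    float32 = list(what = "double", size = 4L),
    float64 = list(what = "double", size = 8L),
    int16   = list(what = "integer", size = 2L),
    uint16  = list(what = "integer", size = 2L, signed = FALSE),
    int32   = list(what = "integer", size = 4L),
    stop("unsupported bit depth; field: dtype = ", dtype))
  endian <- if (is.null(h$endian)) "little" else as.character(h$endian)
  n_expect <- as.integer(h$H) * as.integer(h$W) * as.integer(h$T)
  n_avail <- file.size(path) %/% spec$size
  if (n_avail != n_expect)
    stop(sprintf(
      "dimension mismatch: header implies %d values (H*W*T) but payload holds %d",
      n_expect, n_avail))
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = spec$what, n = n_expect, size = spec$size,
                  signed = !identical(spec$signed, FALSE), endian = endian)
  # payload is frame-major with row-major frames: frame t's pixels are in
  # flat-index order, i.e. columns of the D x T matrix
  mat <- matrix(as.double(vals), nrow = as.integer(h$H) * as.integer(h$W),
                ncol = as.integer(h$T))
  unflatten(mat, as.integer(h$H), as.integer(h$W),
            rate = if (is.null(h$rate)) 1 else as.numeric(h$rate))
}

#' Write a movie as raw binary + JSON sidecar header
#'
#' Inverse of the raw path of [load_video()]: float64 little-endian payload
#' in frame-major order with row-major frames.
#'
#' @param stack a [video_stack()].
#' @param path output payload path; the header is written to `<path>.json`.
#' @export
save_video_raw <- function(stack, path) {
  stopifnot(inherits(stack, "VideoStack"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(flatten(stack)), con, size = 8L, endian = "little")
  jsonlite::write_json(
    list(H = stack$H, W = stack$W, T = stack$T, rate = stack$rate,
         dtype = "float64", endian = "little"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
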