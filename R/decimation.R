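#' Decimation specification
#'
#' Bundles the temporal factor `k` (frames per block), the spatial factors
#' `ly`, `lx` (pixels per block edge) and a (row, col) grid `offset` used
#' for interleaved acquisition (typically `floor(l/2)` on each axis for the
#' half-shifted grid).  Block tiling is anchored at `-offset`, so border
#' blocks may be partial; partial blocks average only the pixels they cover.
#'
#' @param k temporal factor, >= 1.
#' @param ly,lx spatial factors, >= 1.
#' @param offset integer (row, col) grid shift, `0 <= offset < (ly, lx)`.
#' @return a `DecimationSpec` list.
#' @export
decimation_spec <- function(k = 1L, ly = 1L, lx = 1L, offset = c(0L, 0L)) {
  k <- as.integer(k); ly <- as.integer(ly); lx <- as.integer(lx)
  offset <- as.integer(offset)
  if (k < 1L || ly < 1L || lx < 1L) stop("k, ly, lx must all be >= 1")
  if (length(offset) != 2L || any(offset < 0L) ||
      offset[1L] >= ly || offset[2L] >= lx)
    stop("offset must lie in [0, block size) on each axis")
  structure(list(k = k, ly = ly, lx = lx, offset = offset),
            class = "DecimationSpec")
}

#' Temporal decimation
#'
#' Aggregates each block of `k` consecutive frames into one frame.  Block
#' `t'` covers frames `[t'k, min((t'+1)k, T))` (0-based); a trailing block
#' shorter than `k` is aggregated over its actual length.  The mean is the
#' default and recommended method; `median` applies per pixel; `subsample`
#' keeps the first frame of each block.
#'
#' @param Y `D x T` matrix (or a [video_stack()], returned as a stack with
#'   rate divided by `k`).
#' @param k block length in frames, >= 1.
#' @param method aggregation rule.
#' @return decimated matrix with `ceiling(T / k)` columns (or stack).
#' @export
decimate_temporal <- function(Y, k, method = c("mean", "median", "subsample")) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (inherits(Y, "VideoStack")) {
    out <- decimate_temporal(flatten(Y), k, method)
    return(unflatten(out, Y$H, Y$W, rate = Y$rate / k))
  }
  Y <- as.matrix(Y)
  if (k == 1L) return(Y)
  T <- ncol(Y)
  Tp <- ceiling(T / k)
  grp <- rep(seq_len(Tp), each = k, length.out = T)
  if (method == "mean") {
    # block sums via matrix product with the (sparse) averaging map
    M <- Matrix::sparseMatrix(i = seq_len(T), j = grp, x = 1, dims = c(T, Tp))
    M <- M %*% Matrix::Diagonal(Tp, 1 / Matrix::colSums(M))
    return(as.matrix(Y %*% M))
  }
  if (method == "subsample")
    return(Y[, (seq_len(Tp) - 1L) * k + 1L, drop = FALSE])
  out <- matrix(0, nrow(Y), Tp)
  for (tp in seq_len(Tp)) {
    idx <- which(grp == tp)
    out[, tp] <- apply(Y[, idx, drop = FALSE], 1, median)
  }
  out
}

block_index <- function(n, l, off) {
  # 0-based input coordinate -> 0-based block index, tiling anchored at -off
  (seq_len(n) - 1L + off) %/% l
}

#' Linear map performing spatial decimation
#'
#' Builds the sparse `D' x D` matrix whose application to a row-major
#' flattened image equals [decimate_spatial()]: each output pixel averages
#' the input pixels of its block (partial border blocks renormalize over the
#' pixels they cover, so every row sums to 1).  The linearity
#' `M (A C) = (M A) C` is the identity underwriting two-phase imaging.
#'
#' @param H,W input grid dimensions.
#' @param ly,lx block edge lengths.
#' @param offset (row, col) grid shift, `0 <= offset < (ly, lx)`.
#' @return a list with the sparse map `M`, output dims `H_out`, `W_out`.
#' @export
decimation_matrix <- function(H, W, ly, lx = ly, offset = c(0L, 0L)) {
  ly <- as.integer(ly); lx <- as.integer(lx); offset <- as.integer(offset)
  if (ly > H || lx > W) stop("block size exceeds grid size")
  if (any(offset < 0L) || offset[1L] >= ly || offset[2L] >= lx)
    stop("offset must lie in [0, block size) on each axis")
  br <- block_index(H, ly, offset[1L])   # block row of each input row
  bc <- block_index(W, lx, offset[2L])
  Hout <- max(br) + 1L
  Wout <- max(bc) + 1L
  # row-major flat indices
  in_d <- rep(seq_len(H) - 1L, each = W) * W + rep(seq_len(W) - 1L, H)
  out_d <- rep(br, each = W) * Wout + rep(bc, H)
  M <- Matrix::sparseMatrix(i = out_d + 1L, j = in_d + 1L, x = 1,
                            dims = c(Hout * Wout, H * W))
  M <- Matrix::Diagonal(nrow(M), 1 / Matrix::rowSums(M)) %*% M
  list(M = M, H_out = Hout, W_out = Wout,
       ly = ly, lx = lx, offset = offset, H = H, W = W)
}

#' Spatial decimation
#'
#' Averages non-overlapping `ly x lx` pixel blocks of every frame (or of
#' every footprint column).  Accepts a [video_stack()] or a `D x m` matrix
#' plus grid metadata; the same sparse linear map is applied column-wise.
#'
#' @param x a [video_stack()] or `D x m` matrix.
#' @param ly,lx block edge lengths.
#' @param offset (row, col) grid shift.
#' @param H,W grid dims (required when `x` is a matrix).
#' @return for a stack input, a decimated [video_stack()]; for a matrix, a
#'   list with the decimated `values` and the new grid dims.
#' @export
decimate_spatial <- function(x, ly, lx = ly, offset = c(0L, 0L),
                             H = NULL, W = NULL) {
  if (inherits(x, "VideoStack")) {
    dm <- decimation_matrix(x$H, x$W, ly, lx, offset)
    out <- as.matrix(dm$M %*% flatten(x))
    return(unflatten(out, dm$H_out, dm$W_out, rate = x$rate))
  }
  if (is.null(H) || is.null(W))
    stop("grid metadata (H, W) required for matrix input")
  dm <- decimation_matrix(H, W, ly, lx, offset)
  list(values = as.matrix(dm$M %*% x), H_out = dm$H_out, W_out = dm$W_out)
}

#' Zero-order-hold spatial upsampling
#'
#' Every full-resolution pixel inherits the value of the decimated-grid
#' block that covers it; the inverse-direction companion of
#' [decimate_spatial()] used when returning from the decimated fitting phase
#' to the full data.
#'
#' @param A_dec `D' x N` matrix on the decimated grid (or vector).
#' @param ly,lx,offset the decimation that produced `A_dec`.
#' @param H,W full-resolution grid dims.
#' @return `D x N` matrix on the full grid.
#' @export
upsample_zoh <- function(A_dec, ly, lx = ly, offset = c(0L, 0L), H, W) {
  A_dec <- as.matrix(A_dec)
  ly <- as.integer(ly); lx <- as.integer(lx); offset <- as.integer(offset)
  br <- block_index(H, ly, offset[1L])
  bc <- block_index(W, lx, offset[2L])
  Hout <- max(br) + 1L; Wout <- max(bc) + 1L
  if (nrow(A_dec) != Hout * Wout)
    stop(sprintf("A_dec has %d rows but the decimated grid is %d x %d",
                 nrow(A_dec), Hout, Wout))
  src <- rep(br, each = W) * Wout + rep(bc, H)  # 0-based coarse index per pixel
  A_dec[src + 1L, , drop = FALSE]
}

#' Truncated-SVD compression of a movie
#'
#' Computes the `M` leading eigenvectors `V` (rows, orthonormal) of the
#' time-by-time covariance `Y'Y` and the projected data `Y V'`, the
#' compression baseline against which decimation is compared.
#'
#' @param Y `D x T` matrix.
#' @param M retained dimension, `1 <= M <= min(D, T)`.
#' @return a `CompressedBasis` list with `V` (`M x T`), `proj` (`D x M`),
#'   `eigenvalues` and `M`.
#' @export
compress_svd <- function(Y, M) {
  Y <- as.matrix(Y)
  M <- as.integer(M)
  if (M < 1L || M > min(dim(Y)))
    stop("M must lie in [1, min(D, T)]")
  e <- eigen(crossprod(Y), symmetric = TRUE)
  V <- t(e$vectors[, seq_len(M), drop = FALSE])
  structure(list(V = V, proj = Y %*% t(V),
                 eigenvalues = e$values[seq_len(M)], M = M,
                 kind = "svd"),
            class = "CompressedBasis")
}

#' Structured random-projection compression
#'
#' Draws a Gaussian probe `Omega` (`T x M`) and takes `L` = orthonormal
#' basis of `range(Y Omega)` via QR; analogously `R` for `Y'`.  A single
#' power-iteration-free sketch; deterministic given `seed`.
#'
#' @param Y `D x T` matrix.
#' @param M sketch dimension, `1 <= M <= min(D, T)`.
#' @param seed RNG seed for the probes.
#' @return a `CompressedBasis` list with `L` (`D x M`, orthonormal columns),
#'   `R` (`M x T`, orthonormal rows), `Omega`, `M`, `seed`.
#' @export
compress_random <- function(Y, M, seed = 0L) {
  Y <- as.matrix(Y)
  M <- as.integer(M)
  if (M < 1L || M > min(dim(Y)))
    stop("M must lie in [1, min(D, T)]")
  L <- with_local_seed(seed, {
    Omega <- matrix(rnorm(ncol(Y) * M), ncol(Y), M)
    qr.Q(qr(Y %*% Omega))[, seq_len(M), drop = FALSE]
  })
  R <- with_local_seed(seed + 1L, {
    Omega2 <- matrix(rnorm(nrow(Y) * M), nrow(Y), M)
    t(qr.Q(qr(crossprod(Y, Omega2)))[, seq_len(M), drop = FALSE])
  })
  Omega <- with_local_seed(seed, matrix(rnorm(ncol(Y) * M), ncol(Y), M))
  structure(list(L = L, R = R, Omega = Omega, M = M, seed = seed,
                 kind = "random"),
            class = "CompressedBasis")
}

# evaluate expr under a temporary RNG state, restoring the caller's state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
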