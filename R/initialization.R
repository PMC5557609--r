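#' Per-pixel noise level from the high-frequency power spectrum
#'
#' Estimates the noise standard deviation of every pixel by averaging its
#' periodogram over a band of high frequencies (default the upper half of
#' the Nyquist range), where calcium signal power is negligible.  Scaled so
#' that i.i.d. Gaussian noise of standard deviation `s` yields an estimate
#' converging to `s` as `T` grows; adding a constant to a trace does not
#' change the estimate (the DC bin is never in the band).
#'
#' @param Y `D x T` matrix or a [video_stack()].
#' @param band frequency interval as a fraction of Nyquist, within (0, 1].
#' @return a `NoiseMap` list: `sigma` (length `D`, >= 0) and `band`.
#' @export
estimate_pixel_noise <- function(Y, band = c(0.5, 1)) {
  if (inherits(Y, "VideoStack")) Y <- flatten(Y)
  Y <- as.matrix(Y)
  T <- ncol(Y)
  if (length(band) != 2L || band[1L] <= 0 || band[2L] > 1 ||
      band[1L] >= band[2L])
    stop("band must be an interval within (0, 1] of Nyquist")
  # one-sided periodogram bins j = 1..floor(T/2) at frequency j/T cycles
  # per sample; Nyquist fraction = 2 j / T
  j <- seq_len(T %/% 2L)
  keep <- j / (T / 2) >= band[1L] & j / (T / 2) <= band[2L]
  if (sum(keep) < 8L)
    stop("trace too short for the requested band (fewer than 8 periodogram bins)")
  ft <- stats::mvfft(t(Y - rowMeans(Y))) # T x D; demeaning only touches DC
  pgram <- Mod(ft[j[keep] + 1L, , drop = FALSE])^2 / T
  structure(list(sigma = sqrt(colMeans(pgram)), band = band),
            class = "NoiseMap")
}

#' @rdname estimate_pixel_noise
#' @param y a single trace.
#' @return for `estimate_trace_noise`, a scalar sigma.
#' @export
estimate_trace_noise <- function(y, band = c(0.5, 1)) {
  estimate_pixel_noise(matrix(y, nrow = 1L), band = band)$sigma
}

# separable Gaussian blur of an H x W image, reflection padding at borders
gaussian_blur <- function(img, sd) {
  hw <- max(1L, as.integer(ceiling(2.5 * sd)))
  kern <- exp(-(seq(-hw, hw))^2 / (2 * sd^2))
  kern <- kern / sum(kern)
  blur_axis <- function(m) {   # blur down the rows of m
    n <- nrow(m)
    idx <- c(rev(seq_len(min(hw, n))), seq_len(n),
             n + 1L - rev(seq_len(min(hw, n))))
    if (hw > n) stop("blur kernel wider than the image")
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(kern))
      out <- out + kern[o] * mp[(o - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(blur_axis(t(blur_axis(img))))
}

#' Greedy detection of component centers
#'
#' Iterates `N` times over a mean-subtracted copy of the movie: each frame
#' is blurred with an isotropic Gaussian of width `expected_radius`, the
#' pixel with the largest temporal energy of the blurred movie is selected
#' (ties broken by the smaller row-major index), a rank-1 (shape, trace)
#' pair is refined on a local window around it and subtracted, and the
#' search repeats.  Centers are returned in selection order.
#'
#' @param Y a [video_stack()] or `D x T` matrix with `H`, `W` given.
#' @param N number of centers to find, `1 <= N <= D`.
#' @param expected_radius Gaussian blur width in pixels (also sets the
#'   refinement window, of half-width `2 * expected_radius`).
#' @param H,W grid dims when `Y` is a matrix.
#' @return a `CenterList`: `centers` (`N x 2` matrix of 0-based (row, col)),
#'   `expected_radius`.
#' @export
greedy_initialize <- function(Y, N, expected_radius = 2, H = NULL, W = NULL) {
  if (inherits(Y, "VideoStack")) { H <- Y$H; W <- Y$W; Y <- flatten(Y) }
  if (is.null(H) || is.null(W)) stop("grid metadata (H, W) required")
  Y <- as.matrix(Y)
  N <- as.integer(N)
  D <- H * W
  if (N < 1L || N > D) stop("N must lie in [1, D]")
  if (all(Y == 0)) stop("degenerate input: all-zero movie")
  T <- ncol(Y)
  R <- Y - rowMeans(Y)                       # mean-subtracted residual
  blur_flat <- function(mat) {
    # blur every column (frame) of a D x m row-major flattened matrix
    out <- mat
    for (t in seq_len(ncol(mat))) {
      img <- matrix(mat[, t], H, W, byrow = TRUE)
      out[, t] <- as.vector(t(gaussian_blur(img, expected_radius)))
    }
    out
  }
  B <- blur_flat(R)
  win <- max(1L, as.integer(round(2 * expected_radius)))
  centers <- matrix(0L, N, 2L)
  for (n in seq_len(N)) {
    energy <- rowSums(B^2)
    d <- which.max(energy) - 1L            # ties: smaller row-major index
    r0 <- d %/% W; c0 <- d %% W
    centers[n, ] <- c(r0, c0)
    rows <- max(0L, r0 - win):min(H - 1L, r0 + win)
    cols <- max(0L, c0 - win):min(W - 1L, c0 + win)
    px <- as.vector(outer(rows * W, cols, "+")) + 1L
    # rank-1 refinement on the local window of the residual
    ctr <- d + 1L
    a <- pmax(R[px, , drop = FALSE] %*% R[ctr, ] , 0)
    a <- as.numeric(a)
    for (it in 1:5) {
      if (sum(a^2) == 0) break
      tr <- crossprod(R[px, , drop = FALSE], a) / sum(a^2)
      a <- pmax(R[px, , drop = FALSE] %*% tr / sum(tr^2), 0)
      a <- as.numeric(a)
    }
    if (sum(a^2) > 0) {
      tr <- as.numeric(crossprod(R[px, , drop = FALSE], a) / sum(a^2))
      R[px, ] <- R[px, ] - a %o% tr
      # keep the blurred movie in sync: blur is linear and frame-wise
      aimg <- numeric(D); aimg[px] <- a
      ab <- as.vector(t(gaussian_blur(matrix(aimg, H, W, byrow = TRUE),
                                      expected_radius)))
      B <- B - ab %o% tr
    }
  }
  structure(list(centers = centers, expected_radius = expected_radius,
                 H = H, W = W),
            class = "CenterList")
}

#' Square support patches around component centers
#'
#' Patch `P_n` is the square window of side `2 h + 1` centered on center
#' `n`, clipped to the grid; the admissible support of footprint `n`.  The
#' background is always supported on the whole grid.
#'
#' @param centers `N x 2` matrix of 0-based (row, col) centers, or a
#'   `CenterList`.
#' @param patch_half_width window half-width `h` in pixels.
#' @param H,W grid dims.
#' @return a `PatchSet`: list `pixels` of 1-based flat index vectors, plus
#'   `centers`, `half_width`, `H`, `W`.
#' @export
build_patches <- function(centers, patch_half_width, H, W) {
  if (inherits(centers, "CenterList")) centers <- centers$centers
  centers <- matrix(as.integer(centers), ncol = 2L)
  h <- as.integer(patch_half_width)
  if (any(centers[, 1L] < 0L) || any(centers[, 1L] >= H) ||
      any(centers[, 2L] < 0L) || any(centers[, 2L] >= W))
    stop("center outside the pixel grid")
  pix <- lapply(seq_len(nrow(centers)), function(n) {
    rows <- max(0L, centers[n, 1L] - h):min(H - 1L, centers[n, 1L] + h)
    cols <- max(0L, centers[n, 2L] - h):min(W - 1L, centers[n, 2L] + h)
    sort(as.vector(outer(rows * W, cols, "+"))) + 1L   # 1-based flat indices
  })
  structure(list(pixels = pix, centers = centers, half_width = h,
                 H = H, W = W),
            class = "PatchSet")
}

#' Initial factor values
#'
#' The spatial background is the per-pixel 20th percentile of the movie
#' over time; the temporal background starts as the all-ones vector; each
#' footprint is an isotropic Gaussian bump of width `expected_radius`
#' truncated to its patch; each trace is the movie at the center pixel,
#' background-subtracted and clamped at zero.
#'
#' @param Y `D x T` matrix or [video_stack()].
#' @param centers a `CenterList` or `N x 2` matrix of 0-based centers.
#' @param patches a [build_patches()] result.
#' @param expected_radius Gaussian bump width (pixels).
#' @param percentile background percentile (default 20).
#' @param H,W,rate grid metadata when `Y` is a matrix.
#' @return a [factor_model()] satisfying all model invariants.
#' @export
initialize_factors <- function(Y, centers, patches, expected_radius = 2,
                               percentile = 20, H = NULL, W = NULL,
                               rate = 1) {
  if (inherits(Y, "VideoStack")) {
    H <- Y$H; W <- Y$W; rate <- Y$rate; Y <- flatten(Y)
  }
  if (is.null(H) || is.null(W)) stop("grid metadata (H, W) required")
  if (inherits(centers, "CenterList")) centers <- centers$centers
  centers <- matrix(as.integer(centers), ncol = 2L)
  N <- nrow(centers)
  T <- ncol(Y)
  b <- apply(Y, 1L, quantile, probs = percentile / 100, names = FALSE)
  b <- pmax(b, 0)
  f <- rep(1, T)
  A <- matrix(0, H * W, N)
  C <- matrix(0, N, T)
  for (n in seq_len(N)) {
    px <- patches$pixels[[n]]
    if (length(px) == 0L) stop("empty patch for component ", n)
    d <- px - 1L
    rr <- d %/% W; cc <- d %% W
    A[px, n] <- exp(-((rr - centers[n, 1L])^2 + (cc - centers[n, 2L])^2) /
                      (2 * expected_radius^2))
    ctr <- centers[n, 1L] * W + centers[n, 2L] + 1L
    C[n, ] <- pmax(Y[ctr, ] - b[ctr], 0)
  }
  factor_model(A, C, b, f, H = H, W = W, rate = rate, patches = patches)
}
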