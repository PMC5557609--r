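#' Factor model for a fluorescence movie
#'
#' The CNMF decomposition `Y ~ A C + b f'`: non-negative spatial footprints
#' `A` (`D x N`), non-negative calcium traces `C` (`N x T`), a non-negative
#' rank-1 spatial background `b` (length `D`) and its unconstrained temporal
#' profile `f` (length `T`).  Grid metadata (`H`, `W`, frame rate) travels
#' with the model so that shapes can be reshaped to images and decimated.
#'
#' @param A `D x N` non-negative matrix of footprints (dense or sparse).
#' @param C `N x T` non-negative matrix of traces.
#' @param b length-`D` non-negative background image.
#' @param f length-`T` background time course (unconstrained sign).
#' @param H,W pixel grid dimensions, `D = H * W`.
#' @param rate frame rate (frames per second).
#' @param patches optional [build_patches()] result giving the admissible
#'   support of each column of `A`.
#' @param ar optional per-neuron AR parameters (see [estimate_ar()]).
#' @return an object of class `FactorModel`.
#' @export
factor_model <- function(A, C, b, f, H, W, rate = 1, patches = NULL,
                         ar = NULL) {
  A <- as.matrix(A); C <- as.matrix(C)
  D <- H * W
  N <- ncol(A)
  if (nrow(A) != D) stop("nrow(A) must equal H * W")
  if (nrow(C) != N) stop("nrow(C) must equal ncol(A)")
  if (length(b) != D) stop("length(b) must equal H * W")
  if (length(f) != ncol(C)) stop("length(f) must equal ncol(C)")
  if (N > 0 && (min(A) < 0 || min(C) < 0))
    stop("A and C must be entrywise non-negative")
  if (length(b) && min(b) < 0) stop("b must be entrywise non-negative")
  structure(
    list(A = A, C = C, b = as.numeric(b), f = as.numeric(f),
         N = N, H = H, W = W, rate = rate, patches = patches, ar = ar),
    class = "FactorModel")
}

#' @export
print.FactorModel <- function(x, ...) {
  cat(sprintf("FactorModel: %d components on a %d x %d grid, T = %d\n",
              x$N, x$H, x$W, ncol(x$C)))
  invisible(x)
}

#' Reconstruction and residual
#'
#' `reconstruct()` forms the denoised movie `A C + b f'` (the decoder of the
#' decimate-then-demix compression scheme); `residual_movie()` subtracts it
#' from the data.
#'
#' @param model a [factor_model()].
#' @param C_source optional trace matrix to use instead of `model$C` (e.g.
#'   traces demixed from decimated data, for reconstruction at full
#'   resolution).
#' @return a [video_stack()] for `reconstruct`; a `D x T` matrix for
#'   `residual_movie`.
#' @export
reconstruct <- function(model, C_source = NULL) {
  C <- if (is.null(C_source)) model$C else as.matrix(C_source)
  if (ncol(C) != length(model$f))
    stop("trace length does not match background time course")
  if (nrow(C) != model$N) stop("component count mismatch")
  Yhat <- model$b %o% model$f
  if (model$N > 0) Yhat <- Yhat + model$A %*% C
  unflatten(Yhat, model$H, model$W, rate = model$rate)
}

#' @rdname reconstruct
#' @param Y `D x T` data matrix (or a [video_stack()]).
#' @export
residual_movie <- function(Y, model, C_source = NULL) {
  if (inherits(Y, "VideoStack")) Y <- flatten(Y)
  Y - flatten(reconstruct(model, C_source))
}

#' Residual sum of squares of a model fit
#'
#' `||Y - A C - b f'||_F^2`, the biconvex objective minimized by the
#' patch-constrained HALS updates.
#'
#' @inheritParams residual_movie
#' @return a scalar RSS.
#' @export
model_rss <- function(Y, model, C_source = NULL) {
  sum(residual_movie(Y, model, C_source)^2)
}

#' Normalize footprints to unit l2-norm
#'
#' Rescales every column of `A` to unit Euclidean norm and moves the scale
#' into the corresponding row of `C` (and spike matrix, if attached), the
#' convention under which components are ranked and \eqn{\Delta F/F} is
#' computed.  Zero columns are left untouched.
#'
#' @param model a [factor_model()].
#' @return the rescaled model.
#' @export
normalize_model <- function(model) {
  if (model$N == 0) return(model)
  nrm <- sqrt(colSums(model$A^2))
  pos <- nrm > 0
  model$A[, pos] <- sweep(model$A[, pos, drop = FALSE], 2, nrm[pos], "/")
  model$C[pos, ] <- sweep(model$C[pos, , drop = FALSE], 1, nrm[pos], "*")
  if (!is.null(model$S))
    model$S[pos, ] <- sweep(model$S[pos, , drop = FALSE], 1, nrm[pos], "*")
  model
}

#' Save / load a fitted model archive
#'
#' The archive is an RDS file with a fixed named layout: `A` as a sparse
#' triplet (`data`, `indices` = 0-based (row, col) pairs, `shape`), dense
#' `C`, `b`, `f`, and a `meta` list (grid dims, rate, patch definitions, AR
#' parameters, spikes and noise levels when present).  `load_model()` is the
#' exact inverse.
#'
#' @param model a [factor_model()].
#' @param path file path of the archive.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "FactorModel"))
  Asp <- as(Matrix::Matrix(model$A, sparse = TRUE), "TsparseMatrix")
  archive <- list(
    A = list(data = Asp@x, indices = cbind(Asp@i, Asp@j),
             shape = dim(model$A)),
    C = model$C, b = model$b, f = model$f,
    meta = list(H = model$H, W = model$W, rate = model$rate,
                patches = model$patches, ar = model$ar,
                S = model$S, sigma = model$sigma,
                version = "demixscale-archive-1"))
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_model
#' @return for `load_model`, the restored [factor_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  archive <- readRDS(path)
  for (f in c("A", "C", "b", "f", "meta"))
    if (is.null(archive[[f]])) stop("archive missing dataset: ", f)
  shp <- archive$A$shape
  A <- matrix(0, shp[1L], shp[2L])
  if (length(archive$A$data))
    A[archive$A$indices + 1L] <- archive$A$data
  m <- archive$meta
  model <- factor_model(A, archive$C, archive$b, archive$f,
                        H = m$H, W = m$W, rate = m$rate,
                        patches = m$patches, ar = m$ar)
  model$S <- m$S
  model$sigma <- m$sigma
  model
}
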