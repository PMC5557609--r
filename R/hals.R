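#' Multi-scale fitting schedule
#'
#' Controls the decimated warm-start phase and the full-resolution
#' refinement of [fit_multiscale()]: temporal factor `k` (default 30
#' frames/block), spatial factors (`ly`, `lx`) (default 3x3 pixel blocks),
#' `dec_sweeps` alternating single-inner sweeps on the decimated data
#' (default 30), `full_sweeps` sweeps on the full data (default 5) with
#' `inner` inner iterations each (default 5), and an early-stopping
#' tolerance on the relative RSS improvement of the full phase.
#'
#' @param k temporal decimation factor.
#' @param ly,lx spatial decimation factors.
#' @param dec_sweeps alternations on decimated data.
#' @param full_sweeps sweeps on full data.
#' @param inner inner iterations per HALS call on full data.
#' @param tol relative-RSS early-stop tolerance for the full phase.
#' @return a `FitSchedule` list.
#' @export
fit_schedule <- function(k = 30L, ly = 3L, lx = 3L, dec_sweeps = 30L,
                         full_sweeps = 5L, inner = 5L, tol = 1e-4) {
  if (any(c(k, ly, lx, dec_sweeps, full_sweeps, inner) < 1L))
    stop("all schedule counts must be >= 1")
  if (tol <= 0) stop("tolerance must be positive")
  structure(list(k = as.integer(k), ly = as.integer(ly), lx = as.integer(lx),
                 dec_sweeps = as.integer(dec_sweeps),
                 full_sweeps = as.integer(full_sweeps),
                 inner = as.integer(inner), tol = tol),
            class = "FitSchedule")
}

# --- internal fast-HALS kernels -------------------------------------------
# Atil = [A b] (D x (N+1)), Ctil = [C; f] ((N+1) x T).  Each row/column
# update is the exact minimizer of ||Y - Atil Ctil||^2 in that coordinate
# block, so the objective never increases.  Components whose column of Atil
# (rows of Ctil for the shape step) have zero squared norm are skipped and
# flagged rather than updated.

hals_activity_core <- function(U, V, Ctil, inner, nonneg = TRUE) {
  Np1 <- nrow(Ctil)
  vd <- diag(V)
  skipped <- which(vd <= 0)
  for (it in seq_len(inner)) {
    for (n in seq_len(Np1)) {
      if (vd[n] <= 0) next
      upd <- Ctil[n, ] + (U[n, ] - as.numeric(V[n, ] %*% Ctil)) / vd[n]
      # background row (n = Np1) is never clamped; neither is any row when
      # fitting sign-indefinite compressed data
      if (nonneg && n < Np1) upd <- pmax(upd, 0)
      Ctil[n, ] <- upd
    }
  }
  list(Ctil = Ctil, skipped = skipped)
}

hals_shape_core <- function(U, V, Atil, masks, inner) {
  Np1 <- ncol(Atil)
  vd <- diag(V)
  skipped <- which(vd <= 0)
  for (it in seq_len(inner)) {
    for (n in seq_len(Np1)) {
      if (vd[n] <= 0) next
      upd <- pmax(Atil[, n] + (U[n, ] - as.numeric(Atil %*% V[, n])) / vd[n], 0)
      if (n < Np1 && !is.null(masks)) {
        keep <- numeric(nrow(Atil))
        keep[masks[[n]]] <- upd[masks[[n]]]
        upd <- keep
      }
      Atil[, n] <- upd
    }
  }
  list(Atil = Atil, skipped = skipped)
}

#' One fast-HALS activity update (all traces, shapes fixed)
#'
#' Updates every trace row of `C` (clamped at zero) and the background time
#' course `f` (unclamped) by exact coordinate minimization, using only the
#' small products `U = [A b]' Y` and `V = [A b]' [A b]` — the large residual
#' movie is never formed.
#'
#' @param Y `D x T` data matrix (or [video_stack()]).
#' @param model a [factor_model()].
#' @param inner number of inner iterations.
#' @return the model with updated `C` and `f`; components with zero-norm
#'   shapes are skipped and listed in `attr(, "skipped")`.
#' @export
hals_activity <- function(Y, model, inner = 1L) {
  if (inherits(Y, "VideoStack")) Y <- flatten(Y)
  Atil <- cbind(model$A, model$b)
  U <- crossprod(Atil, Y)
  V <- crossprod(Atil)
  res <- hals_activity_core(U, V, rbind(model$C, model$f), inner)
  Np1 <- model$N + 1L
  model$C <- res$Ctil[-Np1, , drop = FALSE]
  model$f <- res$Ctil[Np1, ]
  if (length(res$skipped))
    attr(model, "skipped") <- setdiff(res$skipped, Np1)
  model
}

#' One fast-HALS shape update (all footprints, traces fixed)
#'
#' Symmetric to [hals_activity()] with `U = [C; f] Y'` and
#' `V = [C; f] [C; f]'`; every footprint update is clamped at zero and
#' masked to its patch (the background image is clamped but unmasked).
#'
#' @inheritParams hals_activity
#' @param patches a [build_patches()] result (or `NULL` for no masking).
#' @return the model with updated `A` and `b`.
#' @export
hals_shape <- function(Y, model, patches = model$patches, inner = 1L) {
  if (inherits(Y, "VideoStack")) Y <- flatten(Y)
  Ctil <- rbind(model$C, model$f)
  U <- Ctil %*% t(Y)
  V <- tcrossprod(Ctil)
  masks <- if (is.null(patches)) NULL else patches$pixels
  res <- hals_shape_core(U, V, cbind(model$A, model$b), masks, inner)
  Np1 <- model$N + 1L
  model$A <- res$Atil[, -Np1, drop = FALSE]
  model$b <- res$Atil[, Np1]
  if (length(res$skipped))
    attr(model, "skipped") <- setdiff(res$skipped, Np1)
  model
}

# RSS without forming the residual: ||Y||^2 - 2<U, Ctil> + <V, Ctil Ctil'>
rss_from_parts <- function(Y2, U, V, Ctil) {
  as.numeric(Y2 - 2 * sum(U * Ctil) + sum(V * tcrossprod(Ctil)))
}

# alternate activity/shape sweeps on one data matrix; returns updated
# factors plus the per-sweep RSS (computed exactly, after the shape step)
hals_sweeps <- function(Y, Atil, Ctil, masks, sweeps, inner = 1L,
                        tol = 0, nonneg_C = TRUE) {
  Y2 <- sum(Y^2)
  tY <- t(Y)
  rss <- numeric(0)
  for (s in seq_len(sweeps)) {
    U <- crossprod(Atil, Y)
    V <- crossprod(Atil)
    Ctil <- hals_activity_core(U, V, Ctil, inner, nonneg = nonneg_C)$Ctil
    Us <- crossprod(tY, t(Ctil))
    Us <- t(Us)
    Vs <- tcrossprod(Ctil)
    Atil <- hals_shape_core(Us, Vs, Atil, masks, inner)$Atil
    rss[s] <- rss_from_parts(Y2, crossprod(Atil, Y), crossprod(Atil), Ctil)
    if (tol > 0 && s > 1L &&
        (rss[s - 1L] - rss[s]) <= tol * max(rss[s - 1L], .Machine$double.eps))
      break
  }
  list(Atil = Atil, Ctil = Ctil, rss = rss)
}

#' Patch-constrained CNMF fit with the multi-scale schedule
#'
#' The full fitting pipeline: temporally decimate the movie, detect centers
#' greedily, spatially decimate, build patches, initialize factors, run the
#' decimated warm-start sweeps (inner iteration count 1, frequent
#' alternation), return to the full data by zero-order-hold upsampling of
#' the shapes in space and of the traces in time, rebuild full-resolution
#' patches, and refine with a few sweeps of increased inner iteration
#' count.  Deconvolution of the fitted traces is a separate step
#' ([update_temporal_constrained()] / [deconvolve_trace()]).
#'
#' @param stack a [video_stack()] (or `D x T` matrix with `H`, `W`).
#' @param n_components number of components `N`.
#' @param schedule a [fit_schedule()].
#' @param expected_radius expected soma radius in pixels.
#' @param patch_half_width support patch half-width in pixels (>=
#'   `expected_radius`).
#' @param percentile background initialization percentile.
#' @param H,W,rate grid metadata for matrix input.
#' @return a list with `model` (a [factor_model()]) and `trace` (an
#'   `ObjectiveTrace`: `decimated_rss` per decimated sweep, `full_rss` per
#'   full-data sweep).
#' @export
fit_multiscale <- function(stack, n_components, schedule = fit_schedule(),
                           expected_radius = 2, patch_half_width = 8,
                           percentile = 20, H = NULL, W = NULL, rate = 1) {
  if (inherits(stack, "VideoStack")) {
    H <- stack$H; W <- stack$W; rate <- stack$rate
    Y <- flatten(stack)
  } else Y <- as.matrix(stack)
  if (is.null(H) || is.null(W)) stop("grid metadata (H, W) required")
  T <- ncol(Y)
  sch <- schedule

  # lines 1-2: temporal decimation, then greedy center detection
  Yk <- decimate_temporal(Y, sch$k)
  centers <- greedy_initialize(Yk, n_components, expected_radius,
                               H = H, W = W)

  # line 3: spatial decimation
  dm <- decimation_matrix(H, W, sch$ly, sch$lx)
  Yd <- as.matrix(dm$M %*% Yk)
  l <- max(sch$ly, sch$lx)
  cdec <- cbind(centers$centers[, 1L] %/% sch$ly,
                centers$centers[, 2L] %/% sch$lx)

  # lines 4-6: decimated patches and factor initialization
  hdec <- max(1L, as.integer(ceiling(patch_half_width / l)))
  pdec <- build_patches(cdec, hdec, dm$H_out, dm$W_out)
  mdec <- initialize_factors(Yd, cdec, pdec,
                             expected_radius = max(0.5, expected_radius / l),
                             percentile = percentile,
                             H = dm$H_out, W = dm$W_out)

  # lines 7-9: frequent alternation with a single inner iteration
  dec <- hals_sweeps(Yd, cbind(mdec$A, mdec$b), rbind(mdec$C, mdec$f),
                     pdec$pixels, sch$dec_sweeps, inner = 1L)

  # line 10: traces back to full length by zero-order hold in time (repeats
  # each decimated value k times, preserving each neuron's mean)
  Tk <- ncol(Yk)
  idx <- rep(seq_len(Tk), each = sch$k)[seq_len(T)]
  Ctil <- dec$Ctil[, idx, drop = FALSE]

  # line 11: shapes back to the full grid by zero-order hold in space
  Atil <- upsample_zoh(dec$Atil, sch$ly, sch$lx, c(0L, 0L), H, W)

  # lines 12-15: full-resolution patches, then refinement sweeps with
  # increased inner iteration count
  pfull <- build_patches(centers, patch_half_width, H, W)
  full <- hals_sweeps(Y, Atil, Ctil, pfull$pixels, sch$full_sweeps,
                      inner = sch$inner, tol = sch$tol)

  Np1 <- n_components + 1L
  model <- factor_model(pmax(full$Atil[, -Np1, drop = FALSE], 0),
                        pmax(full$Ctil[-Np1, , drop = FALSE], 0),
                        pmax(full$Atil[, Np1], 0), full$Ctil[Np1, ],
                        H = H, W = W, rate = rate, patches = pfull)
  model$centers <- centers
  list(model = model,
       trace = structure(list(decimated_rss = dec$rss, full_rss = full$rss),
                         class = "ObjectiveTrace"))
}

#' Plain constrained fast-HALS fit (no decimation)
#'
#' The degenerate schedule `k = 1`, `l = 1`: greedy initialization on the
#' full data followed by `sweeps` alternating single-inner HALS sweeps.
#' Used as the reference fit against which the decimated warm start is
#' compared.
#'
#' @inheritParams fit_multiscale
#' @param sweeps number of alternating sweeps.
#' @param inner inner iterations per half-sweep.
#' @export
fit_plain <- function(stack, n_components, sweeps = 200L, inner = 1L,
                      expected_radius = 2, patch_half_width = 8,
                      percentile = 20, H = NULL, W = NULL, rate = 1) {
  sch <- fit_schedule(k = 1L, ly = 1L, lx = 1L, dec_sweeps = sweeps,
                      full_sweeps = 1L, inner = inner, tol = 1e-12)
  fit_multiscale(stack, n_components, sch, expected_radius,
                 patch_half_width, percentile, H = H, W = W, rate = rate)
}

#' Fit on compressed data
#'
#' Runs the alternating HALS updates against a compressed representation of
#' the movie.  For the truncated-SVD basis the sweeps operate entirely on
#' the projected data `Y V'` with the traces represented in the compressed
#' time basis (initial compressed background time course `V 1`, no
#' non-negativity on the compressed traces, which are sign-indefinite);
#' traces are mapped back through `V` at the end.  For the random sketch the
#' activity update uses `(L'Y, L'A)` and the shape update `(Y R', C R')`,
#' with the sketched products computed once.
#'
#' @param Y `D x T` data matrix.
#' @param model an initialized [factor_model()].
#' @param basis a [compress_svd()] or [compress_random()] result.
#' @param sweeps number of alternating sweeps.
#' @return a list with the updated `model` (traces clamped at zero to
#'   satisfy the model invariants) and `rss`, the full-data residual sum of
#'   squares of the fit as optimized — for the truncated-SVD route that is
#'   the sign-indefinite-trace parametrization, whose traces are never
#'   clamped during fitting.
#' @export
fit_compressed <- function(Y, model, basis, sweeps = 30L) {
  Y <- as.matrix(Y)
  masks <- if (is.null(model$patches)) NULL else model$patches$pixels
  Np1 <- model$N + 1L
  Atil <- cbind(model$A, model$b)
  if (basis$kind == "svd") {
    V <- basis$V
    Yc <- Y %*% t(V)
    Ctilc <- rbind(model$C, model$f) %*% t(V)
    out <- hals_sweeps(Yc, Atil, Ctilc, masks, sweeps, inner = 1L,
                       nonneg_C = FALSE)
    Ctil <- out$Ctil %*% V
    Atil <- out$Atil
  } else {
    L <- basis$L; R <- basis$R
    LY <- crossprod(L, Y)       # M x T, computed once
    YR <- Y %*% t(R)            # D x M, computed once
    Ctil <- rbind(model$C, model$f)
    for (s in seq_len(sweeps)) {
      LA <- crossprod(L, Atil)
      Ctil <- hals_activity_core(crossprod(LA, LY), crossprod(LA),
                                 Ctil, 1L)$Ctil
      CR <- Ctil %*% t(R)
      Atil <- hals_shape_core(CR %*% t(YR), tcrossprod(CR), Atil,
                              masks, 1L)$Atil
    }
  }
  rss <- sum((Y - Atil %*% Ctil)^2)
  model$A <- pmax(Atil[, -Np1, drop = FALSE], 0)
  model$b <- pmax(Atil[, Np1], 0)
  model$C <- pmax(Ctil[-Np1, , drop = FALSE], 0)
  model$f <- Ctil[Np1, ]
  list(model = model, rss = rss)
}

Y_as_matrix <- function(Y) if (inherits(Y, "VideoStack")) flatten(Y) else Y
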