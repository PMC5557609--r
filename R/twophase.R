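#' Decimate a fitted model's spatial components
#'
#' Applies the spatial decimation map to every footprint column and to the
#' spatial background, leaving traces untouched: `A_l = M A`, `b_l = M b`.
#' Because decimation is linear, decimating the model then reconstructing
#' equals decimating the full reconstruction exactly.  Patches are mapped
#' to the set of coarse blocks their pixels fall into.
#'
#' @param model a [factor_model()] with grid metadata.
#' @param ly,lx block edge lengths.
#' @param offset (row, col) grid shift (half-block for the interleaved
#'   grid).
#' @return a [factor_model()] on the decimated grid.
#' @export
decimate_model <- function(model, ly, lx = ly, offset = c(0L, 0L)) {
  dm <- decimation_matrix(model$H, model$W, ly, lx, offset)
  A_l <- as.matrix(dm$M %*% model$A)
  b_l <- as.numeric(dm$M %*% model$b)
  patches_l <- NULL
  if (!is.null(model$patches)) {
    # coarse support: blocks covering any pixel of the original patch
    map <- integer(model$H * model$W)
    br <- block_index(model$H, ly, offset[1L])
    bc <- block_index(model$W, lx, offset[2L])
    map <- rep(br, each = model$W) * dm$W_out + rep(bc, model$H) + 1L
    pix <- lapply(model$patches$pixels, function(px) sort(unique(map[px])))
    centers_l <- cbind(
      (model$patches$centers[, 1L] + offset[1L]) %/% ly,
      (model$patches$centers[, 2L] + offset[2L]) %/% lx)
    patches_l <- structure(list(pixels = pix, centers = centers_l,
                                half_width = NA_integer_,
                                H = dm$H_out, W = dm$W_out),
                           class = "PatchSet")
  }
  out <- factor_model(A_l, model$C, b_l, model$f,
                      H = dm$H_out, W = dm$W_out, rate = model$rate,
                      patches = patches_l, ar = model$ar)
  out$S <- model$S
  out
}

#' Two-phase demixing of a decimated movie
#'
#' The decoding step of two-phase imaging: with footprints fixed to the
#' decimated shapes identified at full resolution, traces are first
#' estimated by plain NMF without temporal constraints (non-negative `C`,
#' free `f`; iterated [hals_activity()] updates to convergence) and then
#' refined by the noise-constrained sparse temporal update, with noise
#' re-estimated on the decimated data.
#'
#' @param Y_l decimated movie (`D' x T` matrix or [video_stack()]).
#' @param model_l a [factor_model()] on the decimated grid (from
#'   [decimate_model()]); its shapes are never updated.
#' @param ar optional shared `ARModel`; estimated per neuron if `NULL`.
#' @param max_sweeps,tol convergence control of the plain-NMF phase.
#' @param passes block-coordinate passes of the constrained phase.
#' @param sigma per-neuron noise levels for the constrained phase (`NULL`
#'   to re-estimate on the decimated data).
#' @return the model with demixed `C`, spikes `S`, `f`, per-neuron `sigma`.
#' @export
demix_lowres <- function(Y_l, model_l, ar = NULL, max_sweeps = 200L,
                         tol = 1e-9, passes = 2L, sigma = NULL,
                         deconv_tol = 1e-8) {
  if (inherits(Y_l, "VideoStack")) Y_l <- flatten(Y_l)
  T <- ncol(Y_l)
  zero_cols <- which(colSums(model_l$A^2) == 0)
  # phase A: plain NMF for the traces, shapes frozen
  model_l$C <- matrix(0, model_l$N, T)
  model_l$f <- rep(1, T)
  Atil <- cbind(model_l$A, model_l$b)
  U <- crossprod(Atil, Y_l)
  V <- crossprod(Atil)
  Ctil <- rbind(model_l$C, model_l$f)
  Y2 <- sum(Y_l^2)
  rss_prev <- Inf
  for (s in seq_len(max_sweeps)) {
    Ctil <- hals_activity_core(U, V, Ctil, 1L)$Ctil
    rss <- rss_from_parts(Y2, U, V, Ctil)
    if (rss_prev - rss <= tol * max(rss, .Machine$double.eps)) break
    rss_prev <- rss
  }
  model_l$C <- Ctil[seq_len(model_l$N), , drop = FALSE]
  model_l$f <- Ctil[model_l$N + 1L, ]
  # phase B: noise-constrained sparse temporal update
  out <- update_temporal_constrained(Y_l, model_l, ar = ar, sigma = sigma,
                                     passes = passes, tol = deconv_tol)
  if (length(zero_cols)) {
    out$C[zero_cols, ] <- 0
    out$S[zero_cols, ] <- 0
    attr(out, "zero_shape") <- zero_cols
  }
  out
}

#' One-phase baseline: estimate shapes directly from decimated data
#'
#' The failure-prone alternative to two-phase imaging: initialized with the
#' decimated shapes/background and the full-resolution traces, the sparse
#' spatial update is run on the decimated data itself (shapes free).
#' Components whose shape l2-norm collapses below `purge_tol` times its
#' initial value are purged (their signal absorbed by the background); the
#' survivors' traces are then re-estimated by the constrained temporal
#' update.
#'
#' @param Y_l decimated movie.
#' @param model_l initialization: shapes/background decimated from the
#'   full-resolution fit, traces from the full-resolution fit.
#' @param ar optional shared `ARModel`.
#' @param purge_tol purge threshold on the shape-norm ratio (default 1e-3).
#' @param passes temporal passes.
#' @return a list with `model` (all `N` components; purged ones have
#'   all-zero shape and traces) and `purged` (component indices).
#' @export
run_one_phase <- function(Y_l, model_l, ar = NULL, purge_tol = 1e-3,
                          passes = 2L) {
  if (inherits(Y_l, "VideoStack")) Y_l <- flatten(Y_l)
  norm0 <- sqrt(colSums(model_l$A^2))
  model_l <- update_spatial_constrained(Y_l, model_l)
  norm1 <- sqrt(colSums(model_l$A^2))
  purged <- which(norm1 < purge_tol * pmax(norm0, .Machine$double.eps) |
                    norm0 == 0)
  if (length(purged)) {
    model_l$A[, purged] <- 0
    model_l$C[purged, ] <- 0
  }
  if (length(purged) == model_l$N) {
    warning("all components purged; returning background-only model")
    model_l$S <- matrix(0, model_l$N, ncol(model_l$C))
    return(list(model = model_l, purged = purged))
  }
  # survivors' traces are re-estimated from scratch on the decimated data
  # (plain NMF initialization, then the constrained temporal update): the
  # full-resolution traces are only an initialization for the shape update
  model_l <- demix_lowres(Y_l, model_l, ar = ar, passes = passes)
  if (length(purged)) {
    model_l$C[purged, ] <- 0
    model_l$S[purged, ] <- 0
  }
  list(model = model_l, purged = purged)
}

#' Demix an interleaved dual-grid movie
#'
#' Even frames are acquired on the unshifted coarse grid and odd frames on
#' the half-block-shifted grid (frame 0 is even/unshifted).  Shapes are
#' decimated separately per parity; a plain per-parity NMF activity phase
#' initializes the traces; then for every neuron the parity-split residual
#' data is projected onto the parity-specific unit-normalized shapes, two
#' noise levels are estimated, and the trace is deconvolved jointly across
#' parities with the inverse-variance-weighted noise constraint.
#'
#' @param Y_even `D_e x T_e` matrix: decimated even frames (offset 0 grid).
#' @param Y_odd `D_o x T_o` matrix: decimated odd frames (shifted grid).
#' @param model full-resolution [factor_model()] carrying the shapes.
#' @param ly,lx decimation factors; the odd grid is shifted by
#'   `floor(l/2)` on each axis by default.
#' @param ar optional shared `ARModel`.
#' @param max_sweeps,tol plain-NMF phase control.
#' @param offset_odd grid shift of the odd frames (set `c(0, 0)` to image
#'   both parities on the unshifted grid, which reduces to plain demixing).
#' @param sigma optional noise override: a scalar used for both parities of
#'   every neuron (e.g. 0 for noiseless data); `NULL` estimates two levels
#'   per neuron from the projected traces.
#' @return a list with interleaved traces `C`, spikes `S`, per-parity
#'   backgrounds and noise levels.
#' @export
demix_interleaved <- function(Y_even, Y_odd, model, ly, lx = ly, ar = NULL,
                              max_sweeps = 200L, tol = 1e-9,
                              offset_odd = c(ly %/% 2L, lx %/% 2L),
                              sigma = NULL) {
  m_even <- decimate_model(model, ly, lx, c(0L, 0L))
  m_odd <- decimate_model(model, ly, lx, as.integer(offset_odd))
  T_e <- ncol(Y_even); T_o <- ncol(Y_odd)
  T <- T_e + T_o
  N <- model$N
  flag <- which(colSums(m_even$A^2) == 0 & colSums(m_odd$A^2) == 0)

  # phase A: plain NMF per parity (a trace column belongs to one parity)
  fitA <- function(Y_p, m_p, T_p) {
    Atil <- cbind(m_p$A, m_p$b)
    U <- crossprod(Atil, Y_p)
    V <- crossprod(Atil)
    Ctil <- rbind(matrix(0, N, T_p), rep(1, T_p))
    Y2 <- sum(Y_p^2)
    rss_prev <- Inf
    for (s in seq_len(max_sweeps)) {
      Ctil <- hals_activity_core(U, V, Ctil, 1L)$Ctil
      rss <- rss_from_parts(Y2, U, V, Ctil)
      if (rss_prev - rss <= tol * max(rss, .Machine$double.eps)) break
      rss_prev <- rss
    }
    Ctil
  }
  Ct_e <- fitA(Y_even, m_even, T_e)
  Ct_o <- fitA(Y_odd, m_odd, T_o)

  # per-parity projections with unit-normalized shapes
  proj_parity <- function(Y_p, m_p, Ctil_p, n) {
    a <- m_p$A[, n]
    nrm2 <- sum(a^2)
    if (nrm2 == 0) return(rep(0, ncol(Y_p)))
    others <- m_p$A[, -n, drop = FALSE] %*%
      Ctil_p[setdiff(seq_len(N), n), , drop = FALSE] +
      m_p$b %o% Ctil_p[N + 1L, ]
    as.numeric(crossprod(Y_p - others, a)) / nrm2
  }
  C <- matrix(0, N, T)
  S <- matrix(0, N, T)
  sig <- matrix(0, N, 2L, dimnames = list(NULL, c("even", "odd")))
  even_idx <- seq(1L, T, by = 2L)[seq_len(T_e)]
  odd_idx <- seq(2L, T, by = 2L)[seq_len(T_o)]
  for (n in seq_len(N)) {
    if (n %in% flag) next
    ye <- proj_parity(Y_even, m_even, Ct_e, n)
    yo <- proj_parity(Y_odd, m_odd, Ct_o, n)
    if (is.null(sigma)) {
      se <- if (length(ye) >= 32) estimate_trace_noise(ye) else sd(ye)
      so <- if (length(yo) >= 32) estimate_trace_noise(yo) else sd(yo)
    } else {
      se <- sigma; so <- sigma
    }
    y_full <- numeric(T)
    y_full[even_idx] <- ye
    y_full[odd_idx] <- yo
    arn <- if (is.null(ar)) estimate_ar(y_full, sigma = (se + so) / 2) else
      ar_model(ar$gamma[min(n, nrow(ar$gamma)), ])
    dec <- deconvolve_interleaved(ye, yo, list(sigma_even = se,
                                               sigma_odd = so), arn)
    C[n, ] <- dec$c
    S[n, ] <- dec$s
    sig[n, ] <- c(se, so)
  }
  list(C = C, S = S, sigma = sig, flagged = flag,
       model_even = m_even, model_odd = m_odd)
}

#' Rank components by trace peak and footprint compactness
#'
#' After unit-l2 normalization of the footprints (scale moved into the
#' traces), each component scores the product of its trace's maximum value
#' and the l4-norm of its footprint — penalizing overly broad or noisy
#' shapes.  Descending stable order; ties break by component index.
#'
#' @param model a [factor_model()].
#' @return a list with `order` (component indices, best first) and `scores`.
#' @export
rank_components <- function(model) {
  model <- normalize_model(model)
  if (model$N == 0) return(list(order = integer(0), scores = numeric(0)))
  l4 <- colSums(model$A^4)^(1 / 4)
  peak <- apply(model$C, 1L, max)
  scores <- peak * l4
  list(order = order(-scores), scores = scores)
}

#' Relative fluorescence change of one component
#'
#' `(dF/F)_t = (A(:,n)' A(:,n) C(n,t)) / (A(:,n)' b f(t))`: the trace
#' normalized by the baseline fluorescence obtained by projecting the
#' rank-1 background onto the neuron's footprint.  Invariant to the scale
#' split between `A` and `C`.
#'
#' @param model a [factor_model()].
#' @param n component index.
#' @return the dF/F trace; frames with non-positive baseline are set to
#'   `NA` and flagged in `attr(, "flagged")`.
#' @export
compute_dff <- function(model, n) {
  a <- model$A[, n]
  base <- sum(a * model$b) * model$f
  bad <- which(base <= 0)
  out <- sum(a^2) * model$C[n, ] / base
  if (length(bad)) {
    out[bad] <- NA_real_
    attr(out, "flagged") <- bad
    warning(length(bad), " frame(s) with non-positive baseline")
  }
  out
}

# Pearson correlation with the degenerate-variance convention: 0 when
# either series is constant
pearson0 <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

#' Recovery report across decimation factors
#'
#' Per-neuron Pearson correlation between reference traces and the traces
#' recovered from decimated data (denoised `C`, and deconvolved `S` when
#' available), with median and interquartile range per factor; normalized
#' MSE per factor (reference configuration = 1 exactly); purged components
#' carry correlation 0.
#'
#' @param C_ref reference `N x T` trace matrix.
#' @param candidates named list, one entry per decimation factor, each a
#'   list with `C` (required), optionally `S`, `rss` and `purged` indices.
#' @param S_ref optional reference spike matrix.
#' @param rss_ref RSS of the reference configuration (normalizer).
#' @return a `RecoveryReport`: data frame `summary` (per factor: median and
#'   IQR of the trace correlations, same for spikes, normalized MSE) and
#'   list `per_neuron` of correlation vectors.
#' @export
evaluate_recovery <- function(C_ref, candidates, S_ref = NULL,
                              rss_ref = NULL) {
  N <- nrow(C_ref)
  per_neuron <- list()
  rows <- lapply(names(candidates), function(key) {
    cand <- candidates[[key]]
    if (ncol(cand$C) != ncol(C_ref)) stop("length mismatch")
    cors <- vapply(seq_len(N), function(n)
      pearson0(C_ref[n, ], cand$C[n, ]), numeric(1))
    if (length(cand$purged)) cors[cand$purged] <- 0
    scors <- rep(NA_real_, N)
    if (!is.null(cand$S) && !is.null(S_ref)) {
      scors <- vapply(seq_len(N), function(n)
        pearson0(S_ref[n, ], cand$S[n, ]), numeric(1))
      if (length(cand$purged)) scors[cand$purged] <- 0
    }
    per_neuron[[key]] <<- list(C = cors, S = scors)
    q <- quantile(cors, c(0.25, 0.5, 0.75), names = FALSE)
    qs <- if (all(is.na(scors))) rep(NA_real_, 3) else
      quantile(scors, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
    data.frame(factor = key,
               corr_median = q[2], corr_q25 = q[1], corr_q75 = q[3],
               spike_corr_median = qs[2], spike_q25 = qs[1],
               spike_q75 = qs[3],
               nmse = if (is.null(cand$rss) || is.null(rss_ref)) NA_real_
                      else cand$rss / rss_ref,
               n_purged = length(cand$purged))
  })
  structure(list(summary = do.call(rbind, rows), per_neuron = per_neuron),
            class = "RecoveryReport")
}
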