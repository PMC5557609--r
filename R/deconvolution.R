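#' AR(2) calcium dynamics
#'
#' `ar_model()` bundles per-neuron AR coefficients; `ar_matrix()` builds the
#' sparse banded `T x T` matrix `G` with unit diagonal and `-gamma1`,
#' `-gamma2` on the first and second subdiagonals, so that for a column
#' trace `c` the spike signal is `s = G c` (for row-stacked traces `C`,
#' `S = C G'`, computed by [spike_signal()]).
#'
#' @param gamma numeric vector of AR coefficients (length `p`, default
#'   order 2) or an `N x p` matrix with one row per neuron.
#' @return an `ARModel` list with fields `gamma`, `p`.
#' @export
ar_model <- function(gamma) {
  if (is.null(dim(gamma))) gamma <- matrix(gamma, nrow = 1L)
  structure(list(gamma = gamma, p = ncol(gamma)), class = "ARModel")
}

#' @rdname ar_model
#' @param T trace length.
#' @export
ar_matrix <- function(gamma, T) {
  gamma <- as.numeric(gamma)
  p <- length(gamma)
  diags <- c(list(rep(1, T)),
             lapply(seq_len(p), function(i) rep(-gamma[i], T - i)))
  Matrix::bandSparse(T, T, k = -(0:p), diagonals = diags)
}

#' @rdname ar_model
#' @param C `N x T` trace matrix (or a single trace).
#' @export
spike_signal <- function(C, gamma) {
  if (is.null(dim(C))) C <- matrix(C, nrow = 1L)
  G <- ar_matrix(gamma, ncol(C))
  as.matrix(C %*% Matrix::t(G))
}

# poles of 1 - g1 z^-1 - g2 z^-2; stable iff all |pole| < 1
ar_poles <- function(gamma) {
  p <- length(gamma)
  polyroot(c(-rev(gamma), 1))   # roots of x^p - g1 x^(p-1) - ... - gp
}

clip_stable <- function(gamma, max_pole = 0.99) {
  poles <- ar_poles(gamma)
  m <- Mod(poles)
  if (all(m < max_pole + 1e-12)) return(gamma)
  poles <- poles * pmin(1, max_pole / m)
  # rebuild coefficients from the clipped poles
  cf <- Re(poly_from_roots(poles))
  -cf[-1L]
}

poly_from_roots <- function(r) {
  cf <- 1
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  cf
}

#' Estimate AR coefficients of a noisy calcium trace
#'
#' Method-of-moments fit: the empirical autocovariances satisfy the
#' Yule-Walker equations of the underlying AR process at lags >= 1, with
#' the lag-0 autocovariance inflated by the measurement noise variance;
#' the estimate therefore solves the lag `1..p` Yule-Walker system with
#' `sigma^2` subtracted from the lag-0 term.  Coefficients are clipped to
#' the stable region (pole magnitudes < 0.99).
#'
#' @param y noisy fluorescence trace (length >= 100 recommended).
#' @param p AR order (default 2).
#' @param sigma noise standard deviation; estimated from the
#'   high-frequency PSD of `y` if missing.
#' @param lag_max largest autocovariance lag entering the least-squares
#'   system (default `3 p`).
#' @return an `ARModel` with the fitted `gamma` (and `sigma` attached).
#' @export
estimate_ar <- function(y, p = 2L, sigma = NULL, lag_max = 3L * p) {
  y <- as.numeric(y)
  T <- length(y)
  if (is.null(sigma)) sigma <- estimate_trace_noise(y)
  ac <- stats::acf(y, lag.max = lag_max, type = "covariance",
                   plot = FALSE, demean = TRUE)$acf[, 1, 1]
  c0 <- ac[1L] - sigma^2
  # the noise-corrected signal variance must clear the sampling noise of
  # the autocovariance estimate itself, else the Yule-Walker system is
  # numerically meaningless (near-flat or pure-noise trace)
  if (!is.finite(c0) || c0 <= 5 * ac[1L] / sqrt(T)) {
    warning("trace has no detectable autocorrelated signal; ",
            "returning zero AR coefficients")
    return(structure(list(gamma = matrix(0, 1L, p), p = p, sigma = sigma),
                     class = "ARModel"))
  }
  # least-squares Yule-Walker over lags 1..lag_max (overdetermined for
  # robustness), with the noise-corrected value at lag 0
  cc <- c(c0, ac[-1L])
  rows <- seq_len(lag_max)
  X <- outer(rows, seq_len(p), function(k, i) cc[abs(k - i) + 1L])
  g <- tryCatch(as.numeric(qr.solve(X, cc[rows + 1L])),
                error = function(e) rep(0, p))
  g <- clip_stable(g)
  structure(list(gamma = matrix(g, 1L, p), p = p, sigma = sigma),
            class = "ARModel")
}

#' Sparse non-negative deconvolution of one trace
#'
#' Solves the basis-pursuit-denoising problem for a single fluorescence
#' trace: minimize `||G c||_1` subject to `G c >= 0` and the hard noise
#' constraint `||y - c||^2 <= sigma^2 T` (constrained mode), or the
#' penalized form `0.5 ||y - c||^2 + lambda ||G c||_1` subject to
#' `G c >= 0`.  The spike signal is relaxed from non-negative integers to
#' arbitrary non-negative values.  The inner penalized solver is an ADMM on
#' the banded AR system; constrained mode wraps it in a bisection on the
#' sparsity multiplier until the residual constraint is met within 0.1% (or
#' the multiplier hits 0, when the constraint is slack).  `sigma = 0`
#' returns the Euclidean projection of `y` onto `{c : G c >= 0}`.
#'
#' @param y fluorescence trace.
#' @param ar an `ARModel` (or numeric gamma vector).
#' @param sigma trace noise standard deviation (constrained mode).
#' @param mode `"constrained"` (default) or `"penalized"`.
#' @param lambda sparsity multiplier for penalized mode.
#' @param w optional per-sample weights for the residual (used by the
#'   interleaved solver); target then becomes `sum w (y-c)^2 <= T`.
#' @param tol solver tolerance.
#' @param lambda_init warm-start value for the multiplier search.
#' @param maxit iteration cap of the inner solver.
#' @return a `DeconvolvedTrace` list: denoised `c >= 0` is not enforced
#'   entrywise on `c` itself but follows from `G c >= 0` and causality;
#'   spikes `s = G c >= 0`; plus `lambda`, `wrss` (the achieved residual)
#'   and `converged`.
#' @export
deconvolve_trace <- function(y, ar, sigma = 0,
                             mode = c("constrained", "penalized"),
                             lambda = 0, w = NULL, tol = 1e-9,
                             lambda_init = NULL, maxit = 10000L) {
  mode <- match.arg(mode)
  y <- as.numeric(y)
  T <- length(y)
  gamma <- if (inherits(ar, "ARModel")) as.numeric(ar$gamma[1L, ]) else
    as.numeric(ar)
  g1 <- if (length(gamma) >= 1L) gamma[1L] else 0
  g2 <- if (length(gamma) >= 2L) gamma[2L] else 0
  if (is.null(w)) {
    w <- rep(1, T)
    target <- sigma^2 * T
  } else {
    target <- T
  }
  if (sigma < 0) stop("sigma must be >= 0")
  solve1 <- function(lam, warm = NULL, it = maxit) {
    deconv_admm(y, g1, g2, w, lam, maxit = as.integer(it), tol = tol,
                c_warm = warm$c, u_warm = warm$u,
                rho_init = if (is.null(warm)) 1 else warm$rho)
  }
  if (mode == "penalized") {
    out <- solve1(lambda)
    return(finish_deconv(out, lambda))
  }
  out0 <- solve1(0)
  if (out0$wrss >= target * (1 - 1e-3) || target == 0)
    return(finish_deconv(out0, 0))
  # bracket the multiplier at which the residual constraint becomes active,
  # then regula falsi (bisection fallback) on wrss(lambda) - target, warm-
  # starting every solve from the previous one
  scale <- mean(abs(y)) + 1e-12
  lam_lo <- 0; f_lo <- out0$wrss - target
  lam_hi <- if (is.null(lambda_init) || lambda_init <= 0) scale else
    lambda_init
  out_hi <- solve1(lam_hi, out0, it = maxit %/% 2L)
  while (out_hi$wrss < target && lam_hi < scale * 2^40) {
    if (max(out_hi$s) == 0) break   # fully shrunk; constraint unattainable
    lam_lo <- lam_hi; f_lo <- out_hi$wrss - target
    lam_hi <- lam_hi * 4
    out_hi <- solve1(lam_hi, out_hi, it = maxit %/% 2L)
  }
  if (out_hi$wrss < target) return(finish_deconv(out_hi, lam_hi))
  f_hi <- out_hi$wrss - target
  out_best <- out_hi; lam_best <- lam_hi
  warm <- out_hi
  for (i in 1:40) {
    lam <- lam_lo + (lam_hi - lam_lo) * (-f_lo) / (f_hi - f_lo)
    if (!is.finite(lam) || lam <= lam_lo || lam >= lam_hi)
      lam <- (lam_lo + lam_hi) / 2
    out <- solve1(lam, warm)
    warm <- out
    fv <- out$wrss - target
    if (fv > 0) { lam_hi <- lam; f_hi <- fv; out_best <- out; lam_best <- lam }
    else { lam_lo <- lam; f_lo <- fv }
    if (abs(fv) <= 1e-3 * target) {
      out_best <- out; lam_best <- lam; break
    }
  }
  finish_deconv(out_best, lam_best)
}

finish_deconv <- function(out, lambda) {
  structure(list(c = out$c, s = pmax(out$s, 0), lambda = lambda,
                 wrss = out$wrss, converged = out$converged,
                 u = out$u, rho = out$rho),
            class = "DeconvolvedTrace")
}

#' Deconvolution of an interleaved dual-grid trace
#'
#' For interleaved acquisition the effective footprint of a neuron differs
#' between even frames (unshifted grid) and odd frames (half-shifted grid),
#' so the projected trace carries two noise levels.  The hard noise
#' constraint weights each parity's residual by its inverse variance:
#' minimize `||G c||_1` subject to `G c >= 0` and
#' `||y_even - c_even||^2 / sigma_even^2 + ||y_odd - c_odd||^2 /
#' sigma_odd^2 <= T`.  AR coefficients are shared across parities.
#'
#' @param y_even,y_odd projected data at even/odd frames (frame 0 is even,
#'   i.e. the unshifted grid).
#' @param noise list or vector with `sigma_even`, `sigma_odd`.
#' @param ar an `ARModel` or gamma vector.
#' @param tol solver tolerance.
#' @return a `DeconvolvedTrace` over the full interleaved time axis.
#' @export
deconvolve_interleaved <- function(y_even, y_odd, noise, ar, tol = 1e-11) {
  if (is.list(noise)) {
    se <- noise$sigma_even; so <- noise$sigma_odd
  } else { se <- noise[1L]; so <- noise[2L] }
  T <- length(y_even) + length(y_odd)
  y <- numeric(T)
  even_idx <- seq(1L, T, by = 2L)[seq_along(y_even)]
  odd_idx <- seq(2L, T, by = 2L)[seq_along(y_odd)]
  y[even_idx] <- y_even
  y[odd_idx] <- y_odd
  w <- numeric(T)
  w[even_idx] <- 1 / max(se, 1e-12)^2
  w[odd_idx] <- 1 / max(so, 1e-12)^2
  out <- deconvolve_trace(y, ar, sigma = 1, w = w, tol = tol)
  if ((se == 0 || so == 0) && out$wrss > T * (1 + 1e-6))
    warning("zero noise level on one parity with inconsistent data: ",
            "constraint infeasible")
  out
}

#' Noise-constrained sparse temporal update
#'
#' One block-coordinate pass over the neurons of the model: footprints are
#' normalized to unit l2-norm, the contribution of all other components and
#' the background is subtracted from the data, the residual is projected
#' onto the neuron's footprint, and the projected trace is deconvolved
#' under its own noise constraint (noise estimated from the projected
#' trace's high-frequency PSD).  The background time course is then updated
#' by unconstrained least squares.
#'
#' @param Y `D x T` data matrix or [video_stack()].
#' @param model a [factor_model()] (warm start from the HALS phase).
#' @param ar an `ARModel` with one row of `gamma` per neuron, or `NULL` to
#'   estimate per neuron from the projected traces.
#' @param sigma per-neuron noise levels, or `NULL` to estimate.
#' @param passes number of block-coordinate passes (default 2).
#' @param tol per-trace solver tolerance.
#' @return the model with denoised `C`, spikes `S`, per-neuron `sigma` and
#'   `ar` attached, and updated `f`.
#' @export
update_temporal_constrained <- function(Y, model, ar = NULL, sigma = NULL,
                                        passes = 2L, tol = 1e-8) {
  if (inherits(Y, "VideoStack")) Y <- flatten(Y)
  model <- normalize_model(model)
  N <- model$N
  T <- ncol(Y)
  Atil <- cbind(model$A, model$b)
  AtY <- crossprod(Atil, Y)
  AtA <- crossprod(Atil)
  Ctil <- rbind(model$C, model$f)
  S <- matrix(0, N, T)
  gam <- matrix(0, N, max(2L, if (is.null(ar)) 2L else ar$p))
  sig <- numeric(N)
  lam <- rep(NA_real_, N)   # warm-started multiplier across passes
  zero_shape <- which(diag(AtA)[seq_len(N)] <= 0)
  for (pass in seq_len(passes)) {
    for (n in seq_len(N)) {
      if (n %in% zero_shape) next
      yn <- Ctil[n, ] +
        (AtY[n, ] - as.numeric(AtA[n, ] %*% Ctil)) / AtA[n, n]
      sig[n] <- if (is.null(sigma)) estimate_trace_noise(yn) else
        rep(sigma, length.out = N)[n]
      arn <- if (is.null(ar)) estimate_ar(yn, sigma = sig[n]) else
        ar_model(ar$gamma[min(n, nrow(ar$gamma)), ])
      gam[n, seq_len(ncol(arn$gamma))] <- arn$gamma[1L, ]
      dec <- deconvolve_trace(yn, arn, sigma = sig[n], tol = tol,
                              lambda_init = if (is.na(lam[n])) NULL else
                                lam[n])
      lam[n] <- dec$lambda
      Ctil[n, ] <- dec$c
      S[n, ] <- dec$s
    }
    # exact least-squares update of the background time course
    Np1 <- N + 1L
    Ctil[Np1, ] <- Ctil[Np1, ] +
      (AtY[Np1, ] - as.numeric(AtA[Np1, ] %*% Ctil)) / AtA[Np1, Np1]
  }
  model$C <- pmax(Ctil[seq_len(N), , drop = FALSE], 0)
  model$f <- Ctil[N + 1L, ]
  model$S <- S
  model$sigma <- sig
  model$ar <- ar_model(gam)
  if (length(zero_shape)) attr(model, "skipped") <- zero_shape
  model
}

#' Noise-constrained sparse spatial update
#'
#' Per-pixel l1-minimization of the footprint weights with the pixel's
#' residual as a hard constraint: for each pixel `d`, minimize
#' `sum_n A(d, n)` over the components whose patch contains `d` (plus an
#' unpenalized non-negative background weight), subject to
#' `||Y(d,:) - A(d,:) C - b(d) f'|| <= sigma_d sqrt(T)`.  The sparsity
#' multiplier is bisected until the constraint is met within 0.1% or the
#' multiplier hits 0.  Pixels outside every patch get a background-only
#' fit.
#'
#' @param Y `D x T` data matrix or [video_stack()].
#' @param model a [factor_model()] (`C`, `f` fixed).
#' @param noise a `NoiseMap` (or numeric vector of per-pixel sigmas); `NULL`
#'   to estimate from `Y`.
#' @param patches a [build_patches()] result; defaults to the model's.
#' @return the model with updated `A` and `b`.
#' @export
update_spatial_constrained <- function(Y, model, noise = NULL,
                                       patches = model$patches) {
  if (inherits(Y, "VideoStack")) Y <- flatten(Y)
  if (is.null(noise)) noise <- estimate_pixel_noise(Y)
  sig <- if (inherits(noise, "NoiseMap")) noise$sigma else as.numeric(noise)
  D <- nrow(Y); T <- ncol(Y); N <- model$N
  # membership: which components may load on each pixel
  members <- vector("list", D)
  if (!is.null(patches)) {
    for (n in seq_len(N))
      for (d in patches$pixels[[n]])
        members[[d]] <- c(members[[d]], n)
  } else if (N > 0) {
    members <- rep(list(seq_len(N)), D)
  }
  f <- model$f
  C <- model$C
  ff <- sum(f^2)
  A_new <- matrix(0, D, N)
  b_new <- numeric(D)
  gram_cache <- new.env(parent = emptyenv())
  for (d in seq_len(D)) {
    yd <- Y[d, ]
    cand <- members[[d]]
    if (length(cand) == 0L) {
      b_new[d] <- max(0, sum(yd * f) / ff)
      next
    }
    key <- paste(cand, collapse = ",")
    G <- gram_cache[[key]]
    if (is.null(G)) {
      X <- rbind(C[cand, , drop = FALSE], f)   # rows: candidates then bkg
      G <- list(XX = tcrossprod(X), X = X)
      gram_cache[[key]] <- G
    }
    fit <- nn_lasso_pixel(yd, G$X, G$XX, sig[d]^2 * T)
    A_new[d, cand] <- fit$coef[seq_along(cand)]
    b_new[d] <- fit$coef[length(cand) + 1L]
  }
  model$A <- A_new
  model$b <- b_new
  model
}

# non-negative l1-penalized least squares for one pixel with the last
# coefficient (background) unpenalized, bisecting lambda to hit the
# residual target ||y - X'a||^2 <= target within 0.1%
nn_lasso_pixel <- function(y, X, XX, target, max_cd = 5000L) {
  m <- nrow(X)
  Xy <- as.numeric(X %*% y)
  yy <- sum(y^2)
  live <- which(diag(XX) > 0)     # all-zero rows keep coefficient 0
  cd_solve <- function(lam, a) {
    penal <- c(rep(lam, m - 1L), 0)
    for (it in seq_len(max_cd)) {
      delta <- 0
      for (jj in live) {
        g <- Xy[jj] - sum(XX[jj, ] * a) + XX[jj, jj] * a[jj]
        new <- max(0, (g - penal[jj]) / XX[jj, jj])
        delta <- max(delta, abs(new - a[jj]) * sqrt(XX[jj, jj]))
        a[jj] <- new
      }
      if (delta < 1e-12 * (1 + sqrt(yy))) break
    }
    a
  }
  rss_of <- function(a) yy - 2 * sum(a * Xy) + as.numeric(a %*% XX %*% a)
  a0 <- cd_solve(0, numeric(m))
  r0 <- rss_of(a0)
  if (r0 >= target * (1 - 1e-3) || target == 0)
    return(list(coef = a0, lambda = 0, rss = r0))
  lam_hi <- max(abs(Xy)) + 1e-12
  a_hi <- cd_solve(lam_hi, a0)
  while (rss_of(a_hi) < target && any(a_hi[seq_len(m - 1L)] > 0)) {
    lam_hi <- lam_hi * 2
    a_hi <- cd_solve(lam_hi, a_hi)
  }
  if (rss_of(a_hi) < target)
    return(list(coef = a_hi, lambda = lam_hi, rss = rss_of(a_hi)))
  lam_lo <- 0; a_best <- a_hi; lam_best <- lam_hi
  for (i in 1:50) {
    lam <- (lam_lo + lam_hi) / 2
    a <- cd_solve(lam, a_best)
    r <- rss_of(a)
    if (r > target) { lam_hi <- lam; a_best <- a; lam_best <- lam }
    else lam_lo <- lam
    if (abs(r - target) <= 1e-3 * target) {
      a_best <- a; lam_best <- lam; break
    }
  }
  list(coef = a_best, lambda = lam_best, rss = rss_of(a_best))
}
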