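#' Synthetic scene specification
#'
#' Parameters of the ground-truth fluorescence scene generator: grid,
#' number of neurons and their footprint family, spike statistics, calcium
#' dynamics (AR(2) recursion or an explicit response kernel), rank-1
#' background and noise model.  Defaults emulate nuclear-localized
#' GCaMP-type recordings at cellular resolution.
#'
#' @param H,W pixel grid.
#' @param N number of neurons.
#' @param T frames.
#' @param rate frames per second.
#' @param radius footprint radius parameter in pixels (Gaussian width, or
#'   ring radius for the annular family).
#' @param footprint `"gaussian"` (cytosolic) or `"annular"` (nuclear ring).
#' @param spike_rate expected spikes per frame per neuron.
#' @param min_spikes every neuron is resampled until it fires at least this
#'   many spikes.
#' @param gamma AR(2) coefficients of the calcium dynamics (ignored when
#'   `kernel` is given).
#' @param kernel optional explicit calcium response kernel (numeric
#'   vector); traces are then spike trains convolved with it.
#' @param amplitude median peak amplitude of the transients (fluorescence
#'   a.u.).
#' @param amplitude_sdlog log-normal spread of per-neuron peak amplitudes
#'   around `amplitude` (0 = identical brightness; recordings have a wide
#'   brightness distribution, which is what component ranking exploits).
#' @param baseline mean level of the background image.
#' @param min_sep minimum center separation in pixels (rejection
#'   sampling).
#' @param n_overlap_pairs number of deliberately overlapping neuron pairs
#'   placed at `overlap_sep` pixels.
#' @param overlap_sep separation of the overlapping pairs.
#' @param noise list: `kind` in `c("none", "gaussian", "poisson")`, `sigma`
#'   (gaussian), `nu` (Poisson offset: photon count not due to calcium).
#' @param centers optional `N x 2` matrix of explicit (row, col) neuron
#'   centers, bypassing rejection placement (for constructed geometries).
#' @param seed RNG seed; the scene is deterministic given the spec.
#' @return a `SceneSpec` list.
#' @export
scene_spec <- function(H = 64L, W = 64L, N = 10L, T = 400L, rate = 20,
                       radius = 2.5, footprint = c("gaussian", "annular"),
                       spike_rate = 0.02, min_spikes = 3L,
                       gamma = c(1.7, -0.712), kernel = NULL,
                       amplitude = 1, amplitude_sdlog = 0, baseline = 1,
                       min_sep = 7, n_overlap_pairs = 0L, overlap_sep = 4,
                       noise = list(kind = "gaussian", sigma = 0.1),
                       centers = NULL, seed = 1L) {
  footprint <- match.arg(footprint)
  if (spike_rate < 0) stop("spike rate must be >= 0")
  if (is.null(kernel)) {
    if (any(Mod(ar_poles(gamma)) >= 1)) stop("unstable AR parameters")
  }
  structure(as.list(environment()), class = "SceneSpec")
}

ring_profile <- function(dist2, radius) {
  # annular "nuclear" profile: bright ring at ~radius, dimmer center
  r <- sqrt(dist2)
  w <- radius / 2.5
  exp(-(r - radius)^2 / (2 * w^2)) + 0.3 * exp(-dist2 / (2 * (radius / 2)^2))
}

#' Generate a ground-truth scene
#'
#' Deterministic given the spec's seed.  Footprints are placed by
#' minimum-separation rejection sampling (overlapping pairs, when
#' requested, are placed explicitly at the prescribed separation); spikes
#' are Bernoulli per frame at the requested rate with log-normal
#' amplitudes, resampled until each neuron reaches `min_spikes`; calcium
#' follows the AR(2) recursion (or kernel convolution) and is peak-scaled
#' to `amplitude`; the rank-1 background is a smooth spatial field times a
#' slow temporal profile; Gaussian noise adds i.i.d. `N(0, sigma^2)`,
#' Poisson noise draws `P(nu + signal) - nu` so that the mean equals the
#' noiseless movie.
#'
#' @param spec a [scene_spec()].
#' @return a `GroundTruthBundle`: `A_true` (`D x N`), `C_true`, `S_true`,
#'   `b_true`, `f_true`, `noiseless` and `noisy` (both `D x T`), `centers`,
#'   plus the `spec`.  The noiseless movie equals
#'   `A_true C_true + b_true f_true'` exactly.
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  with_local_seed(spec$seed, make_scene_impl(spec))
}

make_scene_impl <- function(spec) {
  H <- spec$H; W <- spec$W; N <- spec$N; T <- spec$T
  D <- H * W
  margin <- ceiling(spec$radius * 2)
  n_pairs <- spec$n_overlap_pairs
  if (2L * n_pairs > N) stop("more overlapping pairs than neurons")
  if (!is.null(spec$centers)) {
    centers <- matrix(as.numeric(spec$centers), ncol = 2L)
    if (nrow(centers) != N) stop("centers must have N rows")
    return(finish_scene(spec, centers))
  }
  centers <- matrix(NA_real_, 0L, 2L)
  tries <- 0L
  draw <- function() c(runif(1, margin, H - 1 - margin),
                       runif(1, margin, W - 1 - margin))
  ok_sep <- function(p, sep) {
    nrow(centers) == 0L ||
      all(sqrt(rowSums(sweep(centers, 2L, p)^2)) >= sep)
  }
  # overlapping pairs first: anchor + partner at overlap_sep
  for (i in seq_len(n_pairs)) {
    repeat {
      tries <- tries + 1L
      if (tries > 5000L) stop("cannot place footprints at requested separation")
      p <- draw()
      if (!ok_sep(p, spec$min_sep)) next
      ang <- runif(1, 0, 2 * pi)
      q <- p + spec$overlap_sep * c(cos(ang), sin(ang))
      if (q[1] < margin || q[1] > H - 1 - margin ||
          q[2] < margin || q[2] > W - 1 - margin) next
      # partner must be close to its anchor but clear of everyone else
      if (ok_sep(q, spec$min_sep)) {
        centers <- rbind(centers, p, q)
        break
      }
    }
  }
  while (nrow(centers) < N) {
    tries <- tries + 1L
    if (tries > 20000L) stop("cannot place footprints at requested separation")
    p <- draw()
    if (ok_sep(p, spec$min_sep)) centers <- rbind(centers, p)
  }
  finish_scene(spec, centers)
}

finish_scene <- function(spec, centers) {
  H <- spec$H; W <- spec$W; N <- spec$N; T <- spec$T
  D <- H * W
  rr <- rep(0:(H - 1L), each = W)
  cc <- rep(0:(W - 1L), H)
  A <- matrix(0, D, N)
  for (n in seq_len(N)) {
    d2 <- (rr - centers[n, 1L])^2 + (cc - centers[n, 2L])^2
    prof <- if (spec$footprint == "gaussian")
      exp(-d2 / (2 * spec$radius^2)) else ring_profile(d2, spec$radius)
    prof[d2 > (4 * spec$radius)^2] <- 0   # compact support
    A[, n] <- prof / max(prof)
  }
  # spikes and calcium; per-neuron brightness is log-normal around the
  # median amplitude (real recordings span a wide brightness range)
  sdl <- if (is.null(spec$amplitude_sdlog)) 0 else spec$amplitude_sdlog
  amp <- spec$amplitude * exp(rnorm(N, 0, sdl))
  S <- matrix(0, N, T)
  C <- matrix(0, N, T)
  for (n in seq_len(N)) {
    for (try in seq_len(1000L)) {
      sp <- (runif(T) < spec$spike_rate) * exp(rnorm(T, 0, 0.3))
      if (sum(sp > 0) >= spec$min_spikes) break
      if (try == 1000L)
        stop("cannot draw the requested minimum spike count at this rate")
    }
    tr <- if (is.null(spec$kernel)) {
      as.numeric(stats::filter(sp, spec$gamma, method = "recursive"))
    } else {
      as.numeric(stats::convolve(sp, rev(spec$kernel), type = "open"))[seq_len(T)]
    }
    pk <- max(tr)
    scl <- if (pk > 0) amp[n] / pk else 1
    C[n, ] <- tr * scl
    S[n, ] <- sp * scl
  }
  if (!is.null(spec$kernel)) S <- NULL   # spikes in kernel mode are sp, kept below
  # rank-1 background: smooth spatial field, slow temporal drift
  b <- spec$baseline *
    (1 + 0.3 * exp(-((rr - H / 2)^2 + (cc - W / 2)^2) / (2 * (H / 2)^2)))
  f <- 1 + 0.05 * sin(2 * pi * seq_len(T) / T)
  noiseless <- A %*% C + b %o% f
  noisy <- apply_scene_noise(noiseless, spec$noise)
  structure(list(A_true = A, C_true = C,
                 S_true = if (is.null(spec$kernel)) S else NULL,
                 b_true = b, f_true = f,
                 noiseless = noiseless, noisy = noisy,
                 centers = centers, spec = spec),
            class = "GroundTruthBundle")
}

#' Apply a noise model to a noiseless movie
#'
#' Gaussian: adds i.i.d. `N(0, sigma^2)`.  Poisson: draws
#' `P(nu + signal) - nu`, where `nu` is the photon count not due to calcium
#' fluorescence (dark counts and background light), so that the mean equals
#' the noiseless movie while the variance grows with the signal.
#'
#' @param noiseless `D x T` matrix.
#' @param noise list with `kind` and parameters (`sigma` or `nu`).
#' @return noisy `D x T` matrix.
#' @export
apply_scene_noise <- function(noiseless, noise) {
  kind <- if (is.null(noise$kind)) "none" else noise$kind
  switch(kind,
    none = noiseless,
    gaussian = {
      if (is.null(noise$sigma)) stop("gaussian noise needs 'sigma'")
      noiseless + matrix(rnorm(length(noiseless), 0, noise$sigma),
                         nrow(noiseless))
    },
    poisson = {
      nu <- if (is.null(noise$nu)) 0 else noise$nu
      lam <- nu + noiseless
      if (min(lam) < 0) stop("Poisson intensity nu + signal must be >= 0")
      matrix(rpois(length(lam), as.vector(lam)), nrow(noiseless)) - nu
    },
    stop("unknown noise kind: ", kind))
}

#' Reshuffled-residual surrogate movie
#'
#' Builds a semi-synthetic movie whose ground truth is the fitted model:
#' per pixel, the residual time series is partitioned into equal-count
#' strata by rank of the reconstructed signal (ties broken by frame index),
#' permuted within each stratum, and added back to the reconstruction —
#' preserving each pixel's residual multiset exactly and the link between
#' noise variance and signal mean up to stratum granularity.
#'
#' @param Y `D x T` matrix or [video_stack()].
#' @param model the [factor_model()] fitted on `Y`.
#' @param strata number of strata (default 200; reduced to `floor(T/5)`
#'   with a warning when `T < strata`).
#' @param seed RNG seed for the within-stratum permutations.
#' @return the surrogate `D x T` matrix.
#' @export
reshuffle_residual <- function(Y, model, strata = 200L, seed = 0L) {
  if (inherits(Y, "VideoStack")) Y <- flatten(Y)
  T <- ncol(Y)
  strata <- as.integer(strata)
  if (T < strata) {
    strata <- max(1L, T %/% 5L)
    warning("T < strata; reduced to ", strata, " strata")
  }
  recon <- flatten(reconstruct(model))
  resid <- Y - recon
  with_local_seed(seed, {
    out <- recon
    # equal-count strata by rank of the reconstructed signal
    sizes <- rep(T %/% strata, strata)
    extra <- T %% strata
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    grp_template <- rep(seq_len(strata), sizes)
    for (d in seq_len(nrow(Y))) {
      ord <- order(recon[d, ], seq_len(T))   # ties by frame index
      shuffled <- resid[d, ]
      for (g in seq_len(strata)) {
        idx <- ord[grp_template == g]
        if (length(idx) > 1L) shuffled[idx] <- shuffled[sample(idx)]
      }
      out[d, ] <- recon[d, ] + shuffled
    }
    out
  })
}

#' Fit a calcium response kernel by linear regression
#'
#' Least-squares deconvolution of a fluorescence trace against the
#' convolution matrix of its spike-count train:
#' `k = argmin_k || y - s * k ||^2`.  A rank-deficient design (e.g. a
#' single spike too close to the end) returns the minimum-norm solution
#' with a warning.
#'
#' @param y fluorescence trace (length `T`).
#' @param s spike counts per frame (length `T`, at least one spike).
#' @param L kernel length, `L <= T`.
#' @return the fitted kernel (length `L`).
#' @export
fit_response_kernel <- function(y, s, L) {
  T <- length(y)
  if (L > T) stop("kernel length exceeds trace length")
  if (all(s == 0)) stop("spike train has no spikes")
  X <- matrix(0, T, L)
  for (j in seq_len(L)) X[j:T, j] <- s[seq_len(T - j + 1L)]
  sv <- svd(X)
  tolr <- max(dim(X)) * .Machine$double.eps * sv$d[1L]
  pos <- sv$d > tolr
  if (sum(pos) < L)
    warning("rank-deficient design; returning minimum-norm kernel")
  as.numeric(sv$v[, pos, drop = FALSE] %*%
               ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
}

.scene_cache <- new.env(parent = emptyenv())

#' The standard synthetic benchmark scene
#'
#' A fixed, seeded 128 x 128 scene with `N = 40` neurons (including 4
#' deliberately overlapping pairs), `T = 1000` frames at 20 Hz, AR(2)
#' calcium dynamics, a rank-1 background and Gaussian noise with standard
#' deviation half the median peak pixel amplitude of the transients.
#' Repeated calls return the identical bundle (cached).
#'
#' @param noise_kind `"gaussian"` (the standard condition), `"poisson"`
#'   (offset-subtracted counts with matched mean; the Gaussian-matched
#'   variance analog is built by [apply_scene_noise()]), or `"none"`.
#' @return a `GroundTruthBundle` (see [make_scene()]).
#' @export
standard_scene <- function(noise_kind = c("gaussian", "poisson", "none")) {
  noise_kind <- match.arg(noise_kind)
  key <- paste0("std_", noise_kind)
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  spec <- scene_spec(H = 128L, W = 128L, N = 40L, T = 1000L, rate = 20,
                     radius = 2.5, spike_rate = 0.02, min_spikes = 3L,
                     gamma = c(1.7, -0.712), amplitude = 30,
                     amplitude_sdlog = 0.6, baseline = 30,
                     min_sep = 9, n_overlap_pairs = 4L, overlap_sep = 4,
                     noise = list(kind = "none"), seed = 20170803L)
  bundle <- make_scene(spec)
  # noise level tied to the signal: sigma = 0.5 x median peak pixel
  # amplitude of the neurons' transients
  peak <- apply(bundle$A_true, 2L, max) * apply(bundle$C_true, 1L, max)
  sigma <- 0.5 * median(peak)
  noise <- switch(noise_kind,
    none = list(kind = "none"),
    gaussian = list(kind = "gaussian", sigma = sigma),
    poisson = list(kind = "poisson", nu = 10))
  bundle$noisy <- with_local_seed(spec$seed + 1L,
                                  apply_scene_noise(bundle$noiseless, noise))
  bundle$sigma <- sigma
  bundle$spec$noise <- noise
  .scene_cache[[key]] <- bundle
  bundle
}
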