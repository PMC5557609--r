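# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a small, quiet scene for unit tests
tiny_scene <- function(seed = 7L, noise = list(kind = "gaussian", sigma = 0.5)) {
  make_scene(scene_spec(H = 32L, W = 32L, N = 4L, T = 200L, radius = 2,
                        spike_rate = 0.04, amplitude = 8, baseline = 4,
                        min_sep = 10, noise = noise, seed = seed))
}

# noiseless scene with strictly positive traces (baseline calcium floor so
# non-negativity clamps never activate during HALS) and a constant
# background time course (so every initialization vector lies in the data's
# row space, making lossless compression an exact reparametrization)
positive_scene <- function(seed = 9L) {
  fixture(paste0("pos", seed), function() {
    sc <- make_scene(scene_spec(H = 24L, W = 24L, N = 3L, T = 120L,
                                radius = 2, spike_rate = 0.05, amplitude = 6,
                                baseline = 3, min_sep = 9,
                                noise = list(kind = "none"), seed = seed))
    sc$C_true <- sc$C_true + 1          # positive floor on every trace
    sc$f_true <- rep(1, ncol(sc$C_true))
    sc$noiseless <- sc$A_true %*% sc$C_true + sc$b_true %o% sc$f_true
    sc$noisy <- sc$noiseless
    sc
  })
}

# greedy matching of fitted components to ground-truth neurons by
# footprint correlation (full-resolution shapes)
match_to_truth <- function(Ahat, A_true) {
  N <- ncol(A_true)
  used <- integer(0)
  idx <- integer(N)
  for (n in seq_len(N)) {
    cc <- as.numeric(cor(A_true[, n], Ahat))
    cc[used] <- -2
    idx[n] <- which.max(cc)
    used <- c(used, idx[n])
  }
  idx
}

trace_cors <- function(C_true, C_hat, idx) {
  vapply(seq_len(nrow(C_true)), function(n)
    suppressWarnings({
      v <- stats::cor(C_true[n, ], C_hat[idx[n], ])
      if (is.na(v)) 0 else v
    }), numeric(1))
}

# the shared heavy fixtures for the acceptance suite: the standard scene,
# its phase-1 multi-scale fit, and the component-to-truth matching
std_gaussian <- function() fixture("std_g", function() standard_scene("gaussian"))

std_fit <- function() {
  fixture("std_fit", function() {
    sc <- std_gaussian()
    fit <- fit_multiscale(unflatten(sc$noisy, 128, 128, rate = 20), 40,
                          fit_schedule(k = 30, ly = 3, lx = 3,
                                       dec_sweeps = 30, full_sweeps = 5,
                                       inner = 5),
                          expected_radius = 2.5, patch_half_width = 8)
    fit$idx <- match_to_truth(fit$model$A, sc$A_true)
    fit
  })
}

std_ar <- function() ar_model(c(1.7, -0.712))
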