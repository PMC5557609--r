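---
title: "Multi-scale constrained NMF demixing of calcium imaging video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale constrained NMF demixing of calcium imaging video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demixscale)
```

## The model

A fluorescence movie with `D = H * W` pixels and `T` frames is flattened
(row-major, `d = row * W + col`) into a `D x T` matrix `Y` and modeled as

    Y = A C + b f' + E,

where the columns of `A >= 0` (`D x N`) are the spatial footprints of `N`
neurons, the rows of `C >= 0` (`N x T`) their calcium concentration over
time, `b >= 0` and `f` a rank-1 spatial/temporal background, and `E`
zero-mean noise with diagonal covariance.  Each footprint is constrained to
a square patch around its detected center, which enforces locality and
sparsity of `A` by construction.  The fit minimizes the residual sum of
squares `||Y - A C - b f'||^2` over this constraint set; the problem is
biconvex, and block-coordinate descent alternates exact single-row (trace)
and single-column (footprint) minimizations ("fast HALS"): all traces are
updated with shapes fixed, then all shapes with traces fixed, using only
the small cross-products `A'Y`, `A'A`, `C Y'`, `C C'` — the full residual
movie is never formed.

Calcium dynamics are modeled as a second-order autoregression driven by a
non-negative spike signal,

    C(n, t) = gamma1 C(n, t-1) + gamma2 C(n, t-2) + S(n, t),  S >= 0,

written `s = G c` with a banded matrix `G` (unit diagonal, `-gamma1`,
`-gamma2` on the first two subdiagonals for column traces).  Spike
magnitudes are relaxed from integers to arbitrary non-negative values.

## The multi-scale schedule

`fit_multiscale()` exploits the redundancy of calcium video: the movie is
first decimated in time (mean over blocks of `k = 30` frames by default)
and in space (mean over `3 x 3` pixel blocks), and 30 cheap alternating
sweeps with a single inner iteration are run on the small movie.  Shapes
are then upsampled by zero-order hold, traces are extended by zero-order
hold in time (which preserves each neuron's mean — the printed schedule is
ambiguous between this and a constant per-neuron mean; the constant variant
discards all dynamics and was rejected), and 5 final sweeps with 5 inner
iterations refine the factors on the full data.  Mean decimation is the
default aggregation; median and first-frame subsampling are provided for
comparison, with the documented tie rule that `subsample` keeps the first
frame of each block.  Partial border blocks (which arise for interleaved
grid offsets) average only the pixels they cover, so constant images stay
constant under any block geometry.

Two properties make this work and are asserted by the test suite:

* every HALS update is the exact minimizer of its coordinate block, so the
  RSS is monotone non-increasing within each phase;
* spatial decimation is linear, `M (A C) = (M A) C` exactly, so a model of
  the decimated movie is the decimated model of the full movie.

The decimated warm start typically reaches the same (or a slightly better)
RSS than hundreds of plain full-resolution sweeps; the acceptance suite
checks a ratio of at most 1.02 against a 200-sweep plain fit.

## Initialization

Centers are detected greedily on the temporally decimated movie: each frame
is blurred with an isotropic Gaussian of width `expected_radius`, the pixel
with maximal temporal energy is taken (ties break at the smaller row-major
index; the blur uses reflection padding), a rank-1 (shape, trace) pair is
refined on a local window and subtracted, and the search repeats `N` times.
`N` is user-supplied; automatic model-order selection is out of scope.
Factors initialize as: spatial background = per-pixel 20th percentile,
temporal background = all-ones vector, footprints = Gaussian bumps
truncated to their patches, traces = background-subtracted movie at the
center pixels, clamped at zero.

Per-pixel noise is estimated from the mean periodogram over the upper half
of the Nyquist band (`band = c(0.5, 1)`), scaled so white noise of standard
deviation `s` estimates `s`; the estimate ignores additive constants and
slow signal by construction.  The band default follows the usual
convention for this estimator and is validated on white noise and on a
slow sinusoid plus noise.

## Constrained deconvolution

After the HALS phase, traces are denoised and deconvolved under hard noise
constraints, giving a parameter-free convex program per trace:

    minimize ||G c||_1   subject to  G c >= 0,  ||y - c||^2 <= sigma^2 T.

The per-trace solver is an ADMM on the banded system (a pentadiagonal
Cholesky factorization makes each iteration O(T); over-relaxation with
parameter 1.8 and residual balancing of the penalty parameter accelerate
convergence), wrapped in a bracketed regula-falsi search on the sparsity
multiplier until the residual budget is met within 0.1% or the multiplier
hits zero (the constraint is then slack).  `sigma = 0` reduces to the
Euclidean projection of `y` onto the cone `{c : G c >= 0}`.  Tolerances:
the ADMM stops when primal and dual residuals fall below `tol` times the
trace's amplitude scale (default `1e-9` for single traces, `1e-8` inside
the demixing pipeline); tests that assert exactness at `1e-6` run the
solver at `1e-12`.  A dense coordinate-descent quadratic program on the
impulse-response basis serves as the independent optimality oracle in the
tests, never as the implementation.

AR coefficients are estimated once per neuron and then frozen: an
overdetermined least-squares Yule-Walker system over lags `1..3p` with the
lag-0 autocovariance corrected by the noise variance `sigma^2` (noise
inflates only lag 0).  An exactly determined lag-`1..p` system is markedly
less stable for slow dynamics (poles near 1).  Traces whose corrected
signal variance does not clear the sampling noise of the autocovariance
estimate (`5 / sqrt(T)` of the raw variance) are flagged and get zero
coefficients.  Estimates are clipped to pole magnitudes below 0.99.

The spatial analog minimizes `||A||_1` per pixel over the components whose
patch contains the pixel (plus an unpenalized non-negative background
weight) subject to that pixel's noise budget, again by bisection on the
multiplier to 0.1%.  The `l1` penalty is applied to `A` only — the printed
objective names `||A||_1` — and the background stays unpenalized.

## Two-phase imaging, one-phase baseline, interleaving

The headline protocol: (1) image at standard resolution and fit the model;
(2) image spatially decimated by `l` (an `l^2`-fold pixel-budget saving)
and demix the coarse movie with the *decimated* full-resolution shapes
(`A_l = M A`), first by plain non-negative trace updates to convergence,
then by the noise-constrained temporal update with noise re-estimated on
the coarse data.  Component identity is inherited from phase 1, so no
matching problem arises.

The one-phase baseline estimates shapes directly from the coarse data: the
sparse spatial update runs on `Y_l` (initialized with the decimated shapes
and the full-resolution traces), components whose shape norm collapses
below `1e-3` of its initial value are purged (their signal absorbed by the
background), and the survivors' traces are re-estimated *from scratch* by
plain NMF followed by the constrained update — re-estimation from scratch
is what exposes the baseline's failure on merged shapes; warm-starting from
the full-resolution traces would conceal it.  Purged components score
correlation 0 in recovery reports, and the Pearson correlation of any
constant trace is defined as 0.

Interleaved acquisition alternates between the unshifted coarse grid (even
frames, frame 0) and a half-block-shifted grid (odd frames; both axes are
shifted — single-axis shifts are available via the offset argument).
Parity-specific decimated shapes, two per-neuron noise levels, and an
inverse-variance-weighted noise constraint couple the parities in a single
deconvolution, restoring separability of neurons that share a single
coarse pixel on one grid.

## The synthetic scene generator

No recordings ship with the package; every claim is validated on generated
scenes with known ground truth.  `make_scene()` draws localized
footprints (isotropic Gaussian for cytosolic indicators, or an annular
profile for nuclear-localized ones) with minimum-separation rejection
sampling or explicit centers, Bernoulli spike trains with log-normal
amplitudes (resampled until each neuron reaches a minimum spike count),
AR(2) or measured-kernel calcium dynamics, a smooth rank-1 background, and
Gaussian or offset-Poisson noise (`P(nu + signal) - nu`, mean-preserving
with signal-dependent variance).  `reshuffle_residual()` builds
semi-synthetic movies from a fitted model by permuting per-pixel residuals
within 200 equal-count strata ranked by the reconstructed signal (ties
break by frame index), preserving each pixel's residual multiset exactly
and the noise-variance-vs-signal-mean link up to stratum granularity; any
finer mean-variance coupling is deliberately not modeled.

`standard_scene()` is the fixed benchmark: 128 x 128 pixels, 40 neurons of
radius 2.5 px including 4 overlapping pairs at 4 px separation, 1000
frames at 20 Hz, dynamics `gamma = (1.7, -0.712)` (pole time constants of
roughly 1 s and 0.2 s at 20 Hz, GCaMP6-like), spike rate 0.02 per frame
(~0.4 Hz), median peak amplitude 30 over a baseline of 30 (transients of
order the baseline, with log-normal brightness spread `sdlog = 0.6` across
neurons — recordings span a wide brightness range, which is what component
ranking reflects), and Gaussian noise with `sigma` equal to half the
median peak pixel amplitude.  The Poisson variant uses a dark-count offset
`nu = 10`; the matched-variance Gaussian control sets `sigma^2` to the
mean Poisson variance.

What passing on these scenes does and does not show: the generator follows
the fitted model's own assumptions (linear fluorescence, rank-1
background, spatially uncorrelated noise, independent spike trains, no
motion, no bleaching beyond the background drift).  Success here validates
the optimization and the decimation/interleaving logic, not robustness to
motion artifacts, correlated network activity, or non-stationary
backgrounds.  One consequence is visible in the validation itself: with 40
independently firing, spatially scattered neurons on a 128-grid, most
neurons remain identifiable from coarse data even in one-phase mode, so
the one-phase baseline degrades far less dramatically here than on densely
packed cortical or pallial tissue, where dim, correlated, overlapping
components are the norm.

## Problem sizes and numerical choices

The validation suite runs the full pipeline on `standard_scene()`
(128 x 128 x 1000), smaller unit scenes (24-64 px grids, 120-600 frames),
decimation factors `l` in {2, 4, 8} (16 for the interleaving geometry), a
200-sweep plain fit as the warm-start reference, and 50-trace Monte-Carlo
batches for the AR and spike-recovery checks.  Degenerate inputs are
handled explicitly: zero-norm components are skipped and flagged (never
deleted) during HALS; empty candidate sets fall back to background-only
pixel fits; all-zero movies, dimension mismatches and unsupported dtypes
fail with named errors; `N = 0` models round-trip through the archive
format.  Ties are deterministic everywhere (row-major index for peak
selection, first frame for subsampling, frame index for strata ranking).

## Known limitations

* Motion correction, multi-channel and volumetric containers, and
  streaming ingestion are out of scope.
* Group-lasso initialization is not provided (an order of magnitude slower
  than greedy detection for the same purpose).
* The temporal-background row is updated without a non-negativity clamp;
  `f` may be negative where the data demand it.
* Spike counts are real-valued, not integer.
* Only two interleaved grids are supported; more than two offsets are
  untested territory.
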