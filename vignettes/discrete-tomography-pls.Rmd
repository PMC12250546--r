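---
title: "Discrete tomography with parametric level sets: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete tomography with parametric level sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoPLS)
```

## The problem

X-ray tomography recovers a 2-D attenuation image from line-integral
measurements (a *sinogram*). When the scan is *sparse-view* (few angles
over a half or full rotation) or *limited-angle* (angles confined to a
narrow arc), the linear system `y = A x` is severely underdetermined and
classical reconstructions (filtered backprojection, algebraic methods,
even total-variation regularization) show streaks, blur, and missing
boundaries.

*Discrete tomography* adds a strong prior: the object consists of a few
materials whose gray levels `u0 < u1 (< u2)` are known in advance —
typical of industrial CT of machined parts, micro-CT of bone, or imaging
of a nut (shell / kernel / air). tomoPLS exploits that prior with a
parametric level-set (PLS) representation solved as a compressed-sensing
problem.

## The image model

A two-material image is written as

    u(x, alpha) = u0 (1 - H(phi(x, alpha) - c)) + u1 H(phi(x, alpha) - c)

where `phi` is a scalar level-set field, `c > 0` a small level offset,
and `H` a smoothed Heaviside step that ramps from 0 to 1 over the band
`[-epsilon, epsilon]`:

    H(t) = 1/2 + t/(2 epsilon) + sin(pi t / epsilon) / (2 pi),  |t| <= epsilon

Its exact derivative, `delta(t) = (1 + cos(pi t/epsilon)) / (2 epsilon)`
on the band and zero outside, makes the analytic gradient of the data
misfit exactly consistent with the objective — the package never uses a
numerically inconsistent delta.

Three materials use two fields with the sign-combination model

    u = u0 + (u1 - u0) H(phi1 - c) + (u2 - u1) H(phi1 - c) H(phi2 - c)

which is algebraically identical to the expanded three-case form (a unit
test asserts the identity to machine precision).

The field itself is parametric: `phi = M alpha`, where the columns of `M`
sample Gaussian radial basis functions, one per pixel (and per scale in
the multiscale variant), on the pixel grid. Optimizing over `alpha`
instead of evolving `phi` pointwise removes the reinitialization
machinery of classical level-set methods and makes sparsity meaningful:
most atoms end up with exactly zero weight.

Reconstruction minimizes

    f(alpha) = 1/2 || y - A u(x, alpha) ||^2 + lambda sum_j ||alpha_j||_1

with the orthant-wise limited-memory quasi-Newton (OWL-QN) algorithm,
and the final image is the hard quantization `u1` where `phi > c`, `u0`
otherwise (three-level analog for two fields). The tie `phi = c` goes to
the background: the object is the *strict* super-level set.

## Tunable parameters

* `epsilon` (default **0.1**, level-set-field units): half-width of the
  Heaviside ramp. Larger values widen the band in which gradients are
  nonzero; smaller values sharpen the model toward the hard threshold.
* `c` (default **0.05**): the level offset. It must be a small positive
  number; the package keeps `epsilon > c` so that a flat field near zero
  sits inside the smoothing band and the first gradients are
  informative. Neither value is prescribed by theory; these defaults are
  the package's choices and are recorded in every result object.
* `gamma` (default **0.1**, normalized-domain units): the Gaussian atom
  width, interpreted in a normalized `[0,1] x [0,1]` image domain (so
  `gamma = 0.1` spans about 6 pixels at 64^2). Widths in `[0.1, 0.5]`
  are the practical trade-off range between boundary detail and
  conditioning; the single-scale default was determined empirically on
  the synthetic suite — exactly the procedure a practitioner follows,
  since no closed-form rule exists — with the smallest value of the
  range resolving non-convex boundary detail best while keeping the
  basis matrix sparse after truncation. `multiscaleGammas()` provides
  the ten-scale ladder equally spaced on `[0.1, 0.5]` (the spacing is a
  package choice) for the richer ten-atoms-per-pixel dictionary.
* `truncation` (default **1e-4**): sampled atom values at or below this
  are dropped. The field error is bounded by `truncation * ||alpha||_1`
  (property-tested), and the basis matrix stays sparse for narrow atoms.
* `lambda`: the l1 weight. Following the usual practice, the package
  scans a grid of several small values — default
  `{1e-4, 3e-4, 1e-3, 3e-3, 1e-2}` — and keeps the best reconstruction
  (`lambdaScan()`). With ground truth available the criterion is mean
  Dice over foreground levels; without it, the data misfit of the
  *quantized* image. Ties pick the larger, sparser `lambda`.
* OWL-QN options: memory **10** curvature pairs (pairs with
  `s'y <= 1e-12` are discarded), Armijo constant **1e-4**, backtracking
  factor **0.5**, stopping at pseudo-gradient sup-norm **1e-6** or
  relative objective change **1e-10**, iteration caps of 500 (library
  default) / 700 (study scripts).

## Initialization

The start `alpha0` is a uniform vector scaled so that the *mean* of
`phi` equals `c`, i.e. the whole domain begins inside the Heaviside
smoothing band. A zero or far-from-band start would make
`delta(phi - c)` vanish everywhere and kill the first gradient; the
banded start instead lets every pixel vote in the first iteration. For
the multiphase model the same constant is used for both blocks, which
makes the initialization symmetric under swapping the two level sets (a
test asserts the resulting invariance of the quantized image).

## The synthetic study conditions

`makeBinaryPhantom()` and `makeThreeLevelPhantom()` generate the test
classes of the simulation studies: a convex disc, an annulus (hole), two
disjoint blobs (disconnection), a star-shaped non-convex blob, a block
letter glyph, and a nested three-level object (shell / kernel / air).
The published phantoms exist only as figures, so these are parametric
stand-ins matching their geometric character (convexity, topology,
discrete levels), not pixel-accurate copies. Ground truth is rasterized
at pixel centers and contains no anti-aliased edges.

Projection noise is zero-mean i.i.d. Gaussian with standard deviation
`sigma = n * max(y)` at levels `n` in {0, 0.01, 0.05, 0.1}. The
reference experiments do not state whether `n` is relative to the
maximum, mean, or per-ray magnitude; the maximum was chosen because it
is scale-free and monotone in `n`. Noise realizations are seeded and
recorded in the sinogram object.

What the generator does **not** emulate: photon-count (Poisson)
statistics, scatter, beam hardening, detector point spread, fan-beam
geometry, or model mismatch between simulation and inversion — the same
exact ray-driven projector generates and inverts the data. Passing the
synthetic suite therefore demonstrates the method's behavior under ideal
discrete-tomography assumptions, not robustness to real-scanner physics.

## Numerical choices

* **Projector.** Exact ray-pixel intersection lengths by Siddon-style
  traversal; the adjoint is exact by construction (tested to 1e-12 on
  random vectors). Angles are equally spaced on the *half-open* range so
  parallel-beam-redundant pairs such as 0 and pi are never both
  sampled. Detector defaults: `ceiling(sqrt(2) * gridSize)` bins at
  1-pixel spacing, covering the image diagonal. Rays that miss the
  image keep their all-zero rows so row indexing stays rigid.
* **Degenerate rays.** A ray lying exactly on a pixel-boundary plane is
  assigned to one of the two adjacent columns; line integrals differ
  there only on a measure-zero set. Tests that compare against analytic
  chords use half-integer detector offsets to stay off the boundary.
* **Quantization tie.** `phi = c` maps to background, matching the
  strict inequality that defines the object region.
* **lambda reuse across noise seeds.** In the noise-robustness study
  the grid scan is run on the first noise realization and the selected
  `lambda` is reused for the remaining realizations: the noise level,
  not the realization, determines the appropriate weight.
* **Degenerate gray levels.** A tied *upper* pair `u1 = u2` is accepted
  in the three-level configuration; the model then collapses to the
  merged two-region object, and a test checks the quantized image
  agrees with the single-level-set reconstruction.
* **Problem sizes.** Study runs use 64^2 grids (the desk-scale version
  of the published 128^2 experiments); analytic and oracle property
  tests run at 16^2 to 32^2. These sizes are the package's choices for
  a reproducible default suite.

## Baselines

`fbpReconstruct()` implements Ram-Lak filtered backprojection
(band-limited ramp kernel applied via FFT, linear detector
interpolation, `pi / n_angles` weighting). `tvReconstruct()` solves
nonnegativity-constrained TV regularization (`lambda = 8e-3`, tolerance
`1e-6` by default) with the Chambolle-Pock primal-dual scheme, isotropic
forward differences, Neumann boundaries, and step sizes from a power
iteration on the stacked operator. Both are reference implementations
for comparison, not tuned competitors; at very large TV weights the
primal iteration approaches the flat image only slowly, which the tests
acknowledge by asserting range shrinkage rather than exact constancy.

## Known limitations

* The objective is nonconvex in `alpha`; OWL-QN finds a local minimum
  whose quality depends on the banded initialization. All reported
  results use the default start.
* At most three gray levels (two level-set fields) are supported.
* Parallel-beam geometry only; the geometry type is an enum so fan-beam
  support would be a non-breaking extension.
* Metrics follow the printed formulas: SSIM is evaluated with *global*
  image statistics by default (the windowed mean is available behind a
  flag for cross-checks), and PSNR uses the declared maximum gray value.
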