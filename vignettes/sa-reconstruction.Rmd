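---
title: "Simulated-annealing reconstruction of impedance tilt series"
author: "satomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated-annealing reconstruction of impedance tilt series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satomo)
```

## The measurement and the inverse problem

A linear array of eight electrodes sits under a thin SiN film; each
electrode is driven at its own frequency (200–270 kHz in 10 kHz steps), and
as the electron beam scans the film, the impedance modulation of each
frequency channel forms one image. Because the beam-to-electrode geometry
differs per electrode, the eight channels are projections of the sample at
eight fixed tilt angles,

```
+27.2, +15.9, +9.8, +3.3, -3.3, -9.8, -15.9, -27.2 degrees,
```

all acquired in a single scan (`default_geometry()`). Reconstructing a 3D
volume from them is limited-angle tomography in an extreme regime: a
±27.2° wedge instead of the ±60–70° of conventional tilt series. Direct
inversion (filtered back projection, SIRT) leaves severe wedge artifacts
here, which is why the package uses stochastic search:
simulated annealing over voxel space with a reprojection error.

The forward model (`project()`, `project_all()`) is a parallel-beam
shear-sum: each z-slice is shifted along the array axis x by
`z * tan(theta)` with linear interpolation and the slices are summed. The
tilt axis is y, so no resampling occurs along scan lines; rotation-based
resampling would blur along y without physical justification for a 1D
electrode array. Mass sheared outside the lateral field of view is
dropped. No `cos(theta)` path-length factor is applied by default: it is a
global per-angle scale absorbed by normalization, and is available as
`pathlength_weighting = TRUE` for users who want arc-length integrals.

## The annealing engine

`reconstruct()` minimizes the residual sum of squares
`E = sum_k sum_px (P_k - I_k)^2` over the eight positions, starting from
an all-zero volume:

1. draw a voxel position uniformly over the volume, and an amplitude
   `a ~ Normal(0, s)`;
2. add `a` times a peak-1 isotropic 3D Gaussian kernel (SD `k` voxels,
   truncated at `2k`, clipped at the faces without renormalization);
3. reproject the *change* only and update `E` incrementally;
4. accept if `dE <= 0`, otherwise accept with Boltzmann probability
   `exp(-dE / T)` against a fresh uniform draw (strict `u < P`);
5. on rejection, restore the volume and cached reprojections exactly.

Temperature, kernel SD and amplitude SD decay geometrically from
`(10, 15, 0.2)` to `(0.1, 2, 0.1)` across the outer cycles
(`anneal_schedule()`, `schedule_at()`); the full-scale protocol runs
100,000 iterations per cycle for 5,000 cycles on a 240³ grid — 36 updates
per voxel on average — and the reduced protocol used throughout the tests
runs 5,000 × 300 on a 48³ grid.

The shared-amplitude Gaussian bump (rather than i.i.d. per-voxel noise in
the kernel footprint) is what makes the incremental error update cheap:
the perturbation is separable, so its projection at any angle factorizes
into a sheared x–z profile times the y profile, and `dE` per angle reduces
to two small sums. The compiled engine exploits exactly this; a pure-R
engine (`engine = "r"`, built on `anneal_step()` / `project_delta()`)
implements the identical contract and consumes the identical random
stream, so the two produce bit-comparable runs and cross-validate each
other in the test suite.

### The intensity scale, and why it matters

The annealing constants are meaningful only relative to the intensity
scale of the input images. `reconstruct()` min–max normalizes the eight
images jointly (one global minimum and maximum, preserving the
inter-position contrast that encodes tilt) onto the 8-bit grey range
[0, 255] — the scale the image-conditioning chain itself outputs after
8-bit conversion. On this scale the perturbation SD of 0.2 grey levels is
a fine adjustment relative to typical voxel values, and `T = 10` is small
against squared-grey-level errors, so the search behaves as a fine-grained
near-greedy descent with occasional thermal escapes; the error falls by
orders of magnitude and then saturates, with reprojection correlations
above 0.95 at every position.

We initially evaluated the alternative convention of normalizing to
[0, 1]. It fails in an instructive way: with errors of order one, the
final temperature 0.1 is *large* relative to the attainable error, and the
Metropolis chain reaches its Boltzmann equilibrium — tripling the
iteration count leaves the final error unchanged, pinned at a thermal
floor well above the noise floor (reprojection correlation ≈ 0.94 on the
reference problem, versus ≈ 0.99 on the 8-bit scale). The 8-bit convention
is therefore both the more faithful reading of the acquisition pipeline
and the only one under which the published constants produce the published
behavior.

### Degenerate inputs and numerical choices

* All-zero (or constant) input series: the zero volume is the global
  optimum; the only accepted moves are thermal acceptances of near-zero
  bumps, and per-position correlations are undefined — they are recorded
  as 0 with a warning.
* A rejected step restores the state bit-exactly (the candidate is never
  written). The cached error and reprojections are validated against
  full recomputation to 1e-6 relative tolerance in the tests.
* Ties: `u < P` strictly; `dE = 0` is accepted as non-uphill.
* `cycles = 1` makes the decay exponent 0/0; the schedule returns the
  initial values.
* One seeded generator drives centers, amplitudes and acceptance draws in
  a fixed per-step order (3 uniforms, 1 normal, then 1 uniform only for
  uphill proposals), so a run is reproducible bit-for-bit from its seed,
  on either engine.

### Optional priors

Two reconstruction options encode physical knowledge about film-mounted
samples and substantially improve *volume* recovery (as opposed to
reprojection fit) in the limited-angle setting:

* `nz` — the reconstruction depth. Samples sit on the film (z = 0) and
  have bounded thickness; restricting the grid to the known support
  removes the deepest part of the missing-wedge null space.
* `clip_negative` — voxel non-negativity, implemented as proposal
  rejection: any proposal that would push a voxel below zero is
  infeasible and rejected before the Boltzmann draw. This preserves the
  exactness of the incremental caches (post-hoc clamping would not) and
  detailed balance on the constrained domain.

Both are off by default; the model itself imposes neither.

## Image preprocessing

The conditioning chain for acquired images (`preprocess_image()`)
is: 7×7 Gaussian smoothing with SD 1.2 px; background removal as the
difference between the narrowly and the broadly (201×201, SD 100 px)
smoothed images; 8-bit conversion with half-away rounding. The
subtraction order is chosen so the result is a structure-preserving
band-pass (narrow minus broad); the opposite order would leave only the
background. Convolutions use half-sample symmetric (reflective) padding:
with a unit-sum symmetric kernel this makes the smoothing operator doubly
stochastic, so constants and the image mean are preserved exactly, and
the broad filter produces no dark frame at the borders. Note the
band-pass cancels smooth backgrounds only at distances greater than the
broad kernel's half-width from the image border — images much smaller
than ~200 px are effectively all border.

## Diagnostics

* `cross_correlation()` / `series_correlations()`: Pearson correlation
  between reprojections and inputs, per position — the convergence
  criterion used throughout. Zero-variance images yield 0 with a warning.
* `history_summary()` and `plot_history()`: initial/final error, the
  error half-life cycle, final temperature and correlations from the
  per-cycle history (which also records overall and uphill-only
  acceptance rates). During a run the *uphill* acceptance rate is not
  monotone — the error scale shrinks as the fit improves, offsetting the
  cooling — but on a frozen error landscape acceptance decays
  monotonically with temperature, which is what the test suite verifies.
* `edge_resolution()`: the edge-spread resolution rule — the distance
  over which the normalized, averaged edge profile falls from 0.75 to
  0.25, crossings located by linear interpolation, plateaus estimated
  from the end thirds of the profile. For a Gaussian edge of SD `s` px
  this equals `2 * qnorm(0.75) * s = 1.349 s` px, which the tests verify
  to 2%. The estimator is validated on synthetic edges only; resolutions
  of physical instruments depend on instrument data.

## Synthetic phantoms

Three generators (`sphere_phantom()`, `emulsion_shell_phantom()`,
`cell_phantom()`) emulate the morphologies the instrument images: 3 µm
polystyrene spheres tangent to the film; an emulsion droplet with a
bright high-impedance rim around a dim interior; and an ellipsoidal cell
resting on the film with a nucleus and bright granules (melanosome-like
puncta) in the cytoplasm. Intensities are impedance-proxy levels —
brighter is higher impedance; the cell uses {0, 0.3, 0.5, 1.0} for
background, cytoplasm, nucleus and granules. `simulate_tilt_series()`
projects a phantom at the eight angles and adds i.i.d. Gaussian noise
with SD expressed as a fraction of the clean dynamic range.

What the phantoms deliberately do not model: instrument drift, stripe
noise, detector blur, electrode crosstalk, or quantitative impedance
values in ohms. A passing phantom round-trip therefore demonstrates the
correctness and convergence of the reconstruction machinery, not
instrument-level accuracy on real specimens.

### Reference problem sizes

The test suite and the acceptance script use a 48³ cell phantom
(12 µm field at 0.25 µm voxels, cell semi-axes 5 × 4 × 2.5 µm, nucleus
radius 1.4 µm, twelve granules of radius 0.5 µm), 2% noise, and the
reduced 5,000 × 300 schedule — about 14 updates per voxel, converging in
under a minute on one CPU while reproducing the full-scale protocol's
qualitative behavior: a rapid error collapse within the first cycles,
slow refinement thereafter, and final reprojection correlations ≥ 0.95
(typically ≈ 0.99) at all eight positions. Smaller 32³ / 16³ / 12³
problems exercise oracles and properties where speed matters more than
fidelity.

On ground-truth recovery: with only a ±27.2° wedge, reprojection
agreement is the primary criterion — the volume itself is identifiable
only up to the null space. Unconstrained reconstructions of a noiseless
two-sphere phantom correlate with the truth at ≈ 0.75 (depth elongation
and compensating ripples); adding the thin-sample priors (`nz` bounded to
the support, non-negativity) raises this above 0.8. Users reconstructing
real film-mounted samples should use both priors when the sample
thickness is known.

## Known limitations

* The missing wedge is irreducible: depth resolution is anisotropic and
  structures elongate along z; no schedule reaches truth-level recovery
  without priors.
* The error model is unweighted least squares; no detector noise model
  or robust loss is offered.
* Kernel clipping at the volume faces slightly biases perturbation mass
  near the boundary (documented, unrenormalized by design).
* Runs are single-threaded; the engine is O(footprint²) per step, and
  full-scale 240³ × 5,000-cycle protocols remain hours-long computations.
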