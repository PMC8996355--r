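---
title: "Multi-resolution diffeomorphic registration with stationary velocity fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution diffeomorphic registration with stationary velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdreg)
```

## The registration model

`mdreg` performs deformable registration of pairs of 3D single-channel
volumes — the intended use case is skull-stripped, affinely aligned,
1 mm³ T1-weighted brain MR images — by estimating a **stationary velocity
field** (SVF) $v$ whose flow at time 1 defines the deformation:

$$\frac{\partial D(t)}{\partial t} = v(D(t)), \qquad D(0) = \mathrm{Id},
\qquad \Phi(v) = D(1).$$

Parameterizing the deformation through a velocity field, and keeping that
field smooth, makes the map a diffeomorphism: smooth, invertible (the
inverse is the flow of $-v$), and fold-free (positive Jacobian determinant
everywhere). The field is integrated numerically by **scaling and
squaring**: $v$ is divided by $2^k$ and the resulting small displacement is
self-composed $k$ times ($k = 7$ by default).

Registration is cast as optimization of a self-supervised objective — no
ground-truth deformations are ever used. For a fixed image $I_f$ and moving
image $I_m$ the loss combines, at every resolution level $l$,

* the negated image similarity between $I_f^l$ and the moving image warped
  by $\Phi(\tilde v_l)$ (forward direction),
* the negated similarity between $I_m^l$ and the fixed image warped by
  $\Phi(-\tilde v_l)$ (inverse direction), and
* a total-variation penalty $\lambda\, \mathrm{TV}(v_l)$ on the incremental
  velocity field of that level.

Here $\tilde v_l = \sum_{i \le l} v_i$ is the *accumulated* velocity field:
each level predicts only the residual velocity not already explained by
coarser levels, with coarser fields upsampled (trilinear, corner-aligned)
before the addition. Optimizing the forward and inverse similarities
jointly from a single velocity field is what gives the method its inverse
consistency.

### Sub-networks and multi-resolution estimation

Incremental fields are regressed by three convolutional sub-networks, all
consuming 2-channel full-resolution input (the current moving image stacked
with the fixed image):

* a shared encoder shape — one stride-2 convolution with 16 filters, then
  three stride-2 convolutions with 32 filters (total downsampling 16×);
* a decoder with $l$ transposed convolutions (32 filters, stride 2), so
  levels 1–3 emit SVFs at 1/8, 1/4 and 1/2 of the input resolution;
* two head convolutions (32, 16 filters) and a 3-channel output
  convolution. All kernels are 3×3×3; all layers except the output use
  LeakyReLU.

Before each finer sub-network runs, the moving image is re-warped at full
resolution by the integrated, upsampled accumulated field of the coarser
levels, so the finer network sees only residual misalignment. The loss
terms at all levels are optimized **jointly** in one backward pass (deep
self-supervision), not stage-wise.

The finest accumulated field lives at 1/2 resolution; it is upsampled to
the full grid, integrated in both directions, and passed through an
in-graph **Gaussian smoothing layer** (σ = 1.732 voxels, 3×3×3 kernel,
renormalized to sum 1) that acts on the deformation itself. Because the
smoothing sits inside the computation graph, optimization and smoothing
interact — the estimated velocities adapt to the smoothing rather than
being smoothed post hoc — which is what suppresses folding without a large
explicit regularization weight.

### Similarity and regularization

The similarity is normalized cross-correlation (NCC). Two variants are
implemented, selected by `ncc_window` in `mdreg_config()`:

* **windowed** (default, 9³): mean over voxels of the local zero-normalized
  cross-correlation within the window, windows cropped at the boundary.
  This is the standard choice for registration of images with spatially
  varying contrast.
* **global**: the Pearson correlation of all voxels; cheaper, and entirely
  adequate for mono-modal images with stationary intensity statistics
  (e.g. the synthetic phantoms).

A small ε = 1e-5 is added to the variance product, so constant regions
contribute 0 rather than dividing by zero. A consequence worth knowing:
in regions (or whole coarse pyramid levels) whose variance is comparable to
ε, the similarity saturates below 1 even for identical images.

The regularizer is the mean (over voxels) absolute forward difference of
all field components along all axes — an $L_1$/total-variation penalty on
the *incremental* field of each level, on its native grid and **in that
grid's voxel units**. Using the mean rather than the sum, and native-grid
units rather than the full-resolution storage units, keeps the term on one
scale across resolutions, so a single λ applies to all levels (the storage
units would inflate coarse-level gradients by the grid-spacing ratio). The default λ = 0.35 is the operating
point at which, in the full-scale model, validation overlap peaks while
deformations remain fold-free; `sweep_lambda()` reproduces that selection
experiment on any pair.

### Coordinate and unit conventions

* Voxel indices are 0-based; a displacement field `u` defines the map
  `x -> x + u(x)` on its own grid, in that grid's voxel units.
* Velocity fields are stored in **full-resolution voxel units at every
  level**, so the multi-level accumulation after upsampling is plain
  addition. They are converted to level-grid units (corner-aligned factor
  $(n_l - 1)/(n_{full} - 1)$ per axis) only when integrated and applied at
  a coarser level.
* Out-of-bounds sampling clamps to the border for both images and fields;
  this avoids injecting background zeros into the NCC statistics. The
  boundary condition of the scaling-and-squaring self-composition is the
  same clamping (a choice; the flow equation itself does not prescribe
  one).
* The Jacobian determinant uses central differences in the interior and
  one-sided differences on faces, applied to the full map
  $x + u(x)$; folding statistics are computed from the **smoothed output
  field**, i.e. the deformation actually applied to images.

## Optimization

Training is self-supervised and pairwise. `mdreg_train()` draws ordered
pairs uniformly from all $n^2$ pairs of the training volumes (self-pairs
included) and performs one Adam step per pair (batch size 1, learning rate
1e-4, β = 0.9/0.999, ε = 1e-8 — only the optimizer and learning rate are
prescribed by the method; the β/ε values are the conventional defaults).
The full-scale protocol runs 150,000 iterations; that is the
`mdreg_config()` default, and desk-scale work overrides it.

`mdreg(fixed, moving, mode = "instance")` optimizes *fresh* zero-initialized
sub-networks on a single pair — conventional iterative registration with a
network-parameterized transform. Because the output convolutions start at
zero, optimization starts exactly at the identity transform. For instance
optimization at phantom scale (32–64 voxels per axis) we default to a
learning rate of 1e-3 and a few hundred iterations; the 1e-4 population
rate is unnecessarily conservative when there is no generalization concern,
and was selected by monitoring loss convergence on self- and phantom
registrations. Inputs are min-max normalized to $[0, 1]$ per volume before
entering the network (full-scale MR pipelines normalize intensities during
preprocessing; the package cannot assume that and so normalizes
internally).

All randomness (initialization, pair sampling) derives from `cfg$seed`;
two runs with the same configuration produce bitwise-identical loss traces
on one CPU thread.

Arbitrary input shapes are handled by symmetric zero-padding up to the next
multiple of 16 (the encoder downsampling factor); all outputs are cropped
back to the input grid.

## Synthetic fixtures: what they do and do not show

`make_phantom()` builds "brain-like" piecewise-homogeneous phantoms —
nested ellipsoidal shells with per-seed random center, orientation and
axes, distinct intensities, Gaussian blur (σ = 1 voxel) and additive noise
(sd 0.02 on a unit intensity scale). `make_random_svf()` draws white
noise, smooths it (σ = 4–6 voxels, on a padded grid so the statistics are
stationary), rescales to a requested maximum displacement amplitude, and
verifies by construction that its integration is fold-free.
`make_pair()` warps a phantom and its labels with such a field to create a
registration problem with known ground truth.

Default study conditions for the end-to-end experiments: 48³ phantom pairs
with warp amplitude 4 voxels and smoothness 6 voxels (amplitudes of 2–4
voxels are large relative to these grids, exercising the coarse levels),
and 32³ pairs for the regularization and ablation comparisons. Smoothness
6 voxels was chosen as a plausible analogue of smooth inter-subject
anatomical variation at this scale; it was fixed before the recovery
experiments and is not adjusted per experiment.

These fixtures exercise every stage — multi-resolution estimation,
integration, bidirectional similarity, smoothing, evaluation — but they are
*not* MR physics: no bias fields, no partial-volume tissue mixtures, no
fine cortical geometry. Passing the phantom experiments demonstrates that
the estimator recovers smooth diffeomorphic warps from image evidence at
desk scale; it does not certify the overlap scores reachable on real
brain cohorts, which require full-scale training on hundreds of images.

## Numerical choices and degenerate inputs

* Scaling-and-squaring step count 7 throughout; the reference
  `svf_flow_euler()` (plain vectorized R, 1024 Euler steps) exists only to
  validate the integrator.
* The 3×3×3 smoothing kernel truncates the σ = 1.732 Gaussian heavily; it
  is renormalized to sum 1 per axis, so constants are preserved exactly.
  The kernel size is part of the model specification, not a free knob.
* Trilinear upsampling is corner-aligned; coincident nodes of an
  axis-aligned refinement reproduce source values exactly.
* Constant images: the ε guard makes all NCC variants return 0 (identical
  constants are neither evidence for nor against alignment).
* Non-finite inputs are rejected at the API boundary; a non-finite loss
  during optimization aborts with the offending term named.
* Label maps are warped with nearest-neighbour interpolation only, so no
  new label values can be invented.

## Design decisions that were genuinely open

* **NCC flavor and window.** Only "normalized cross-correlation" is
  prescribed; both global and windowed variants satisfy that. The default
  is windowed 9³ (field convention for this model family), with `"global"`
  available in the configuration.
* **Where similarity is supervised.** Velocity fields live at 1/8–1/2
  resolution and similarity is scored on the matching pyramid levels; in
  addition a full-resolution bidirectional term is computed from the
  upsampled, smoothed field (`full_res_sim = TRUE`). That term is the path
  through which the smoothing layer receives gradient, realizing in-graph
  smoothing within an end-to-end objective; set it to `FALSE` to supervise
  strictly at the SVF levels.
* **Regularizing $v_l$ rather than $\tilde v_l$**: the penalty applies to
  each increment on its native grid (in native-grid voxel units) — the
  literal reading of the per-level summand — so coarse levels are not
  doubly penalized through the accumulation.
* **No skip connections.** The sub-networks are described layer-by-layer as
  encoder, deconvolutions, head; the U-Net naming is honored in shape
  (contract–expand) only. The layer list is followed.
* **Sub-network inputs at full resolution.** The encoder depth (4 stride-2
  layers for every level) implies full-resolution input for all three
  sub-networks; the warped moving image fed to finer levels is produced by
  integrating the upsampled accumulated field at full resolution, without
  the smoothing layer (smoothing acts on the finest-level output only).
* **Model shape in R.** The package follows the classic modelling idiom:
  `mdreg()` is the fitting function returning a classed object with
  `print`, `summary`, `predict`, `plot` and `residuals` methods;
  `coef` and `simulate` are not provided because a dense deformation model
  has no natural coefficient vector or response-simulation semantics.

## Problem sizes used in the shipped experiments

The test-suite and acceptance experiments run at desk scale, chosen so the
full battery completes on a single CPU: integrator validation on 24³ grids
(20 seeded fields against 1024-step Euler integration), self-registration
at 32³ (200 iterations), ground-truth warp recovery at 48³ (amplitude 4;
a few hundred instance iterations at learning rate 3e-3), and
regularization/ablation comparisons at 32³ over three seeds. The
full-scale protocol (176×192×176 volumes, 150,000 iterations) is expressed
by the defaults of `mdreg_config()` but is not exercised by the tests.

## Known limitations

* Stationary velocity fields trade expressiveness for invertibility; very
  large or locally non-smooth deformations may need time-varying fields.
* The TV penalty is non-differentiable at zero differences; the
  subgradient (sign) is used, which is standard and unproblematic for
  Adam-style optimizers.
* Composition and warping assume a single common voxel grid (affinely
  pre-aligned inputs); there is no physical-space composition across
  differently oriented grids.
* Windowed NCC in large homogeneous regions carries little signal (local
  variance ≈ ε); structure-poor images register by their edges, as with
  any intensity-driven method.
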