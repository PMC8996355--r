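# mdreg — multi-resolution diffeomorphic image registration

`mdreg` registers pairs of 3D single-channel volumes (typically
skull-stripped, affinely aligned T1-weighted brain MR images in NIfTI
format) with **diffeomorphic** deformations: smooth, invertible,
fold-free. It is aimed at neuroimaging workflows that need dense
anatomical correspondence — label propagation, atlas-based analysis,
morphometry — where preserving topology matters as much as overlap scores.

## The model

The deformation is parameterized by a **stationary velocity field** (SVF)
*v*: the spatial map is the time-1 flow of

∂D(t)/∂t = v(D(t)),  D(0) = Id,  Φ(v) = D(1),

computed by scaling and squaring (7 steps). One velocity field yields both
the forward deformation Φ(v) and its inverse Φ(−v).

Velocity fields are estimated by three convolutional sub-networks at 1/8,
1/4 and 1/2 resolution, coarse to fine: each level predicts the
*incremental* velocity not explained by coarser levels, accumulated as
ṽ_l = Σ_{i≤l} v_i, with the moving image re-warped by the coarser-level
deformation before each finer network runs. Optimization is
self-supervised and bidirectional — for each level the loss is

− NCC(I_f^l, I_m^l ∘ Φ(ṽ_l)) − NCC(I_m^l, I_f^l ∘ Φ(−ṽ_l)) + λ·TV(v_l),

summed over levels (deep supervision on an average-pooling image pyramid)
with λ = 0.35 by default. An in-graph Gaussian smoothing layer
(σ = 1.732 voxels, 3³ kernel) applied to the finest-resolution deformation
keeps the result effectively fold-free. Everything — networks, spatial
transformer, scaling-and-squaring, loss — is differentiable, with analytic
backward passes implemented in C++; training uses Adam (lr 1e-4, batch 1
for population training; lr 1e-3 and a few hundred iterations for
per-pair instance optimization).

Two usage modes:

* **instance mode** — optimize fresh networks on one pair (classical
  iterative registration with a network-parameterized transform);
* **feedforward mode** — train once on a set of volumes
  (`mdreg_train()`), then register new pairs in a single forward pass.

## Worked example

Register a synthetic labeled phantom pair with a known smooth warp
(no downloads needed — fixtures are generated in code):

```r
library(mdreg)

pair <- make_pair(shape = c(48, 48, 48), amplitude = 4,
                  smoothness_sigma = 6, seed = 11)
dice_scores(pair$labels_moving, pair$labels_fixed)$mean
#> [1] 0.7920526

fit <- mdreg(pair$fixed, pair$moving,
             cfg = mdreg_config(iterations = 200, learning_rate = 3e-3,
                                lambda = 0.35, seed = 1))
summary(fit)
#> Registration summary (instance mode), grid 48x48x48
#>   displacement voxels: mean 1.372, max 3.647
#>   global NCC: 0.9606 before, 0.9952 after
#>   Jacobian determinant range: [0.547, 1.490]
#>   folding voxels (fixed>0 mask): fwd 0 (0.0000%), inv 0 (0.0000%)
#>   final loss: -7.3726

evaluate_direction(fit, pair$labels_fixed, pair$labels_moving, "forward")
#> Registration evaluation (forward direction)
#>   mean Dice over 3 labels: 0.9128
#>   folding: 0 voxels (0.0000% of mask)
```

Reading of the output: label overlap rises from 0.79 to ≈0.91 while the
Jacobian determinant of the deformation stays strictly positive everywhere
in the head mask (zero folding voxels) — the registration is accurate *and*
diffeomorphic. `predict(fit, x)` warps further volumes or label maps with
the fitted deformation, `fit$inverse_field` carries the inverse map, and
`plot(fit)` shows mid-slice image and Jacobian panels.

## Command-line interface

A thin CLI wraps the same functions (script installed at
`system.file("cli", "mdreg.R", package = "mdreg")`):

```sh
Rscript mdreg.R synth --shape 48 --amplitude 4 --seed 7 --out fixtures/
Rscript mdreg.R register --fixed f.nii.gz --moving m.nii.gz \
        --instance --iters 250 --lambda 0.35 --out result/
Rscript mdreg.R evaluate --result result/ --labels-fixed lf.nii.gz \
        --labels-moving lm.nii.gz --direction both
Rscript mdreg.R sweep-lambda --fixed f.nii.gz --moving m.nii.gz \
        --values 0.1,0.2,0.35,0.5,0.75,1.0
```

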