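---
title: "Motion-corrected unrolled reconstruction: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-corrected unrolled reconstruction: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `mocomodl`: the acquisition and
motion models, the encoding operator and its solvers, the two learned
components, the training procedure, the synthetic-data generator that
stands in for a patient cohort, and every numerical decision a maintainer
might want to revisit.

## Acquisition model

The k-space of a 3D Cartesian whole-heart scan is sampled one interleaf per
heartbeat. The readout direction `x` (foot–head) is always fully sampled;
undersampling happens in the `ky`–`kz` phase-encode plane. Three design
elements shape that plane:

* **Elliptical shutter.** Corners of the rectangular grid outside the
  inscribed ellipse are never acquired, saving a factor 4/π. All nominal
  acceleration factors in this package are quoted against the shutter
  interior; against the full rectangle they are 4/π larger, which is why
  nominal 3, 4 and 7 correspond to effective 3.8, 5.1 and 8.9.
* **Spiral-profile ordering.** Each heartbeat acquires a spiral-like arm of
  phase encodes. The literature leaves the exact ordering proprietary;
  we implement Archimedean arms in normalized elliptical coordinates
  (`θ ≈ φ_h + 2π r`), successive heartbeats rotated by the golden angle
  180°/φ ≈ 111.25°, points assigned to arms greedily (nearest spiral with
  remaining capacity, centre-out). This reproduces the qualitative
  variable-density profile without the vendor ordering logic — eddy-current
  ordering and RR-adaptive interleaf sizing are out of scope.
* **Variable density with a fully sampled centre.** Points inside a disc of
  normalized radius `r_center = 0.1` are always acquired; outside,
  retention probability is proportional to `(1 + β r)^(−γ)` with defaults
  β = 4, γ = 2. The acquisition budget is exact:
  `round(count(shutter)/accel)` unique locations. The density law is our
  choice (the field does not publish one); the defaults keep ≥ 95%
  coverage for `r < 0.1` at nominal 7× by construction.

**Retrospective undersampling.** Training pairs require a 7×-equivalent
subset of a 3–4× scan that preserves the prospective sampling-density
profile. The plane is segmented into elliptic annuli with boundaries
equally spaced in normalized radius (the alternative — equal enclosed
area — is unstated in the literature; equal radius was chosen and is
flagged here). Per annulus, acquired readouts are randomly subset until the
acquired percentage matches the target profile; fractions are compared on
unique locations, not readout multiplicity (the second open choice). The
result is a strict subset of physically acquired readouts — the property
that removes the train/test mismatch artifacts that synthetic k-space
simulation produces. 20 annuli are the full-scale default; the scaled
study uses 10 because its 24 × 16 grid leaves only ~30 shutter points per
annulus, and it averages the target over five trajectory realizations
(mirroring the cohort averaging of the full-scale procedure). On small
grids a target annulus can still exceed the source's acquired count;
`retrospective_undersample(clip = TRUE)` then retains the whole annulus,
and the default (`clip = FALSE`) raises an error naming the annulus.

## Motion model and correction

Per-heartbeat 2D iNAVs are registered by cross-correlation against the
stack-mean template (FFT-based, parabolic sub-pixel refinement; the
registration method is unspecified upstream, and normalized
cross-correlation to the mean template is the standard deterministic
choice). Positions are re-referenced to zero mean. Sign conventions:
`+x` is foot→head; end-expiration is the minimal FH position
(configurable via `end_exp` in `bin_heartbeats()`).

**Translational correction** multiplies every sample by
`exp(2πi k·T_m)` with `k = (k_x, k_y)` in cycles/mm and `T_m` the
heartbeat's position relative to the mean — a unit-modulus factor, so
magnitudes are untouched. The correction is exact for a rigidly
translating object with spatially uniform receive sensitivity; with
spatially varying coils the residual is the coil-profile shift, a genuine
physical limit of the method, not an implementation artifact (our tests
therefore check the exact round trip with a uniform coil).

**Soft-gated binning.** Heartbeats are sorted by FH position and split
into 4 equal-count bins (counts differ by ≤ 1). The soft weight of
heartbeat *i* in bin *b* is 1 for its primary bin and
`exp(−(d_ib/(softness·w_b))²)` otherwise (`d_ib` FH distance to the bin
centre, `w_b` the bin half-width, softness default 0.5). The weight law is
unspecified upstream; a Gaussian with a hard-gating limit at softness → 0
was chosen so tests can recover one-hot binning exactly. "Equally
populated" is enforced on primary counts; soft weights then spill
neighbouring heartbeats into each bin.

**Non-rigid fields.** Inter-bin motion is represented by a stationary
velocity field `v` on the ×2-downsampled grid, integrated to a
diffeomorphism by scaling and squaring: `d ← v/2^n`, then `n = 6`
self-compositions (`d ← d + d∘d`); the inverse field integrates `−v`. Six
steps keep the forward∘inverse composition error well under 0.1 voxel for
velocities up to a quarter of the field of view. Warping is trilinear with
clamp-to-edge reads — clamping avoids injecting zeros into
data-consistency residuals at patch borders. Two adjoints of the warp are
available: the *paper-mode* `M*` (warp by the inverse field — cheap, what
the reconstruction uses) and the *exact* transpose (splatting), which the
operator test harness uses so that adjoint identities hold to 1e−8 and the
dense-matrix oracle to 1e−10.

## Encoding operator and solvers

`E = U F S M` maps the end-expiration volume to the weighted multi-bin,
multi-coil sample vector: warp to each bin (`M`), multiply by each coil
map (`S`), unitary DC-centred 3D FFT (`F`; unitary so `F* = F⁻¹` and the
adjoint and inverse coincide), sample the bin's readouts with soft-gating
weights (`U`). Readouts acquired several times stay separate rows, so
re-acquisition density weighting emerges naturally in `E*`. The soft
weights are applied in both `E` and `E*`, i.e. they enter `E*E` squared —
the least-squares weighting interpretation; the right-hand side follows
the zero-filled form `E*b` with a single weight factor, matching the
published `M*ρ_ZF` construction.

The data-consistency (DC) step solves `E*E ρ = E*b` with plain CG, 3
iterations, warm-started at the previous iterate; the denoiser output
enters only through that warm start (the *paper-literal* mode — the
published DC omits a damping term; the damped MoDL variant
`(E*E + λI)ρ = E*b + λz` is also implemented behind
`recon_config(dc_mode = "modl")`). One subtlety worth recording: the CG
residual 2-norm is **not** monotone for CG — only the energy
`½⟨ρ, E*Eρ⟩ − ⟨ρ, E*b⟩` (equivalently the data residual `‖Eρ − b‖`)
decreases monotonically. `cg_solve()` records both, and the
reconstruction ledger asserts the data-residual version before/after
every DC step.

Per-bin images for motion estimation come from 10-iteration iterative
SENSE (single-bin CG, identity motion, warm-started at the zero-filled
adjoint), downsampled ×2 by average pooling; the resulting displacement
fields are upsampled ×2 trilinearly with values doubled.

**Patching.** Volumes are split along the fully sampled `x` direction
(undersampling artifacts do not propagate along it), processed per patch
and recombined: a 5-voxel layer is discarded from interior patch edges,
retained regions overlap by 4 voxels and overlaps are averaged; the
recombination weights form a partition of unity, so patch-independent
content recombines to machine precision. Full-scale defaults are patch 48
of 272; the scaled study uses patch 16 of 24 with a 2-voxel discard,
preserving the discard/overlap character.

## The learned components

Both networks are small 3-level 3D U-Nets (two convolutions per level,
3×3×3 kernels, leaky-ReLU, 2× average-pool down / trilinear up, skip
concatenation; 8/16 channels in the scaled study). The architecture is a
behavioural contract, not a claim of fidelity to any reference
implementation: acceptance is measured by recovery on phantoms.

* **Motion network**: input two magnitude channels (end-expiration bin,
  moving bin) after joint max-normalization (the normalization is another
  unstated detail; joint normalization preserves inter-image contrast),
  output a 3-channel velocity field. The velocity head is
  zero-initialized, so at initialization every field is exactly identity
  and the whole framework reduces to translational-only correction — a
  property the tests rely on.
* **Denoiser**: input the real and imaginary channels of the DC output,
  residual output (`x + correction`), correction head zero-initialized
  (exact identity at start). The residual form is our choice; it
  stabilizes the unrolled iteration and gives the identity
  initialization.

Since no R autodifferentiation framework is available as a dependency,
the package carries a compact reverse-mode tape (`R/autodiff.R`) with
compiled kernels for convolution, warping (with gradients w.r.t. both
image and displacement), pooling and the complex FFT pair; the unrolled
CG is differentiated through its iterations (no implicit
differentiation). Finite-difference checks of the full end-to-end
gradient are part of the test suite.

## Training

Loss: `L = λ₁ L_mot + λ₂ L_recon + λ₃ L_reg` with λ = (100, 10, 1).
`L_mot` is the Charbonnier distance between the end-expiration reference
and each remaining reference bin warped to end-expiration by the predicted
inverse field, plus a velocity smoothness penalty; `L_recon` the
Charbonnier distance between reference and reconstruction; `L_reg` the
squared ℓ2 norm of all convolution kernels. Charbonnier is defined
`mean(√(x²+ε²) − ε)` with ε = 1e−3 on unit-normalized images, so it tends
to `|x|` for large errors and to `x²/(2ε)` for tiny ones. The smoothness
penalty is the squared forward-difference gradient of the velocity,
weight 0.01 inside `L_mot` (form and weight are unspecified upstream and
configurable). The warped images in `L_mot` are the *reference* bins, not
SENSE reconstructions, following the published wording literally.

One optimization step per sample per epoch on a randomly chosen
readout-direction patch; Adam (the unspecified "first-order adaptive
moment" choice) with the initial rate halved on a fixed epoch schedule.
Full-scale defaults: 1600 epochs, LR 3e−4 halved every 400, 48 × 272 × 128
patches. Divergence (non-finite loss) aborts with the last finite
parameters.

## The synthetic cohort and the scaled study

The phantom is a set of complex-valued soft-edged ellipsoids (torso,
heart, vessels, liver) under the deformation
`u_x = s·A_FH·(1 + ν x̂ + σ ẑ)`, `u_y = s·A_LR` — a bulk FH/LR
translation plus an FH-graded non-rigid stretch (ν) and a mild
AP-dependent shear (σ), analytically invertible so renders and
ground-truth forward/inverse fields are exact. The respiratory signal is a
sinusoid plus linear drift sampled once per heartbeat (matching the
one-motion-state-per-heartbeat granularity of the binning); there is no
cardiac-phase motion because the sequence is ECG-triggered to a quiescent
window. k-space noise is i.i.d. circular complex Gaussian. For purely
translational configurations the moving volumes are generated by exact
Fourier shift of the reference render, making the discrete render the
band-limited object and the shift theorem exact; non-rigid states are
re-rendered analytically.

What the phantom does *not* emulate: bSSFP contrast, T2-preparation and
fat saturation, off-resonance, gradient imperfections, realistic anatomy,
intra-bin (within-heartbeat) motion, and coil-profile motion. Passing
tests therefore demonstrate the correctness of the operators, the
trainability of the framework and the end-to-end recovery behaviour — not
clinical image quality.

The scaled study (`scaled_phantom_study()`) fixes: 24 × 24 × 16 voxels at
2 mm, 2 coils, 20 heartbeats, nominal 3× sources subset to the averaged
7× profile, 4 bins, FH/LR amplitudes 6/2 mm, ν = 0.5, σ = 0.2, noise sd
0.01, per-phantom anatomy jitter (±8% axes, ±2 mm centres), 8 training and
2 held-out phantoms, 40 epochs at LR 2e−3 halved every 15, patch 16.
These sizes are the package's desk-scale choice: large enough that the
seven-fold-equivalent subset aliases visibly and the non-rigid residual
after translational correction is non-trivial, small enough that the
whole study (simulation, training, evaluation) completes in minutes.
Held-out evaluation reports the mean displacement error of the estimated
inter-bin fields inside the heart ROI (in voxels, against the analytic
truth expressed in the translational-corrected frame) and heart-ROI
MSE/SSIM of the reconstruction against the corrected-frame end-expiration
reference, compared with the translational-only zero-filled baseline.

## Evaluation metrics

`roi_metrics()` normalizes each magnitude by its own 99th percentile
within the ROI (reference-anchored scale, so metrics are invariant to
global intensity scaling of either volume — the "individually normalized"
display convention), then reports the mean squared difference and a
single-scale 3D SSIM (Gaussian window σ = 1.5, 7-voxel support,
K₁ = 0.01, K₂ = 0.03, data range 1). `paired_ttest()` is the two-sided
paired t-test, with an explicit degenerate branch for zero-variance
differences. ROI selection, manual in clinical work, uses the phantom's
known heart bounding box (`heart_roi()`).

## Known limitations

* The trajectory ordering is spiral-*like*; it does not reproduce any
  vendor's CASPR ordering exactly, and makes no eddy-current claims.
* The translational correction inherits the usual coil-profile
  approximation (exact only for uniform sensitivity).
* Patch-wise motion estimation sees only the patch's slab; motion is
  assumed expressible per patch, as in training.
* The unrolled output is the end-expiration-frame volume only; other bin
  volumes are internal.
* The autodiff tape holds the full unrolled graph in memory; it is sized
  for desk-scale problems, not for 272³-scale training.
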