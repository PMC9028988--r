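---
title: "Methods: super-resolution cardiac DTI with srcdti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-resolution cardiac DTI with srcdti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srcdti)
```

This vignette is the package's account of the models and numerical choices
behind each stage of the pipeline: phantom synthesis, degradation,
slice-to-stack motion correction, Beltrami-regularized super-resolution
reconstruction, tensor fitting, and helix/transverse-angle analysis. It
also states what the synthetic experiments can and cannot demonstrate
about real scanner data.

## The measurement problem

In-vivo cardiac DTI is acquired as thick slices (2 × 2 × 8 mm³ here):
the through-plane dimension is 4× coarser than in-plane, and it is exactly
the transmural direction of the helix-angle ramp that suffers. The package
implements the remedy of acquiring three orthogonal thick-slice stacks and
reconstructing one 2 mm isotropic volume per diffusion channel by solving

$$\hat\rho \;=\; \arg\min_\rho \sum_{i=1}^{N}
 \lVert D_i B_i T_i \rho - \rho_i \rVert^2
 \;+\; \lambda\, Q(\rho), \qquad
 Q(\rho) = \sum_v \sqrt{1 + \beta^2 \lvert \nabla \rho \rvert^2},$$

with $T_i$ the resampling into stack $i$'s frame, $B_i$ the through-plane
slice profile, $D_i$ the slice decimation, and $Q$ the Beltrami energy.
Defaults $\lambda = 10^{-5}$ and $\beta = 1$.

## Left-ventricle phantom

The ground truth is a semi-ellipsoid wall: the family of shells

$$\Big(\tfrac{x - x_c}{R_{min}+d_r}\Big)^2 +
  \Big(\tfrac{y - y_c}{R_{min}+d_r}\Big)^2 +
  \Big(\tfrac{z - z_c}{R_{max}+d_r}\Big)^2 = 1,
  \qquad d_r \in [0, 14],$$

truncated to the apex-down half $z \le z_c$ (the basal cut plane is not
uniquely determined by "semi-ellipsoid"; the equatorial cut is our
documented, configurable choice). $d_r$ is the distance to the
endocardium in voxels. Defaults: 160 × 160 × 128 voxels of 1 mm,
$R_{min} = 16$, $R_{max} = 60$, wall thickness 14.

Rather than stamping integer shells, `lv_wall_distance()` solves the shell
equation for a *continuous* $d_r$ per voxel by Newton iteration (the shell
value is convex and strictly decreasing in $d_r$, so the iteration is
globally convergent from the Euclidean initial guess). Mask membership
uses $d_r \in [0, 14]$, and the continuous wall fraction
$d_r/14 \in [0,1]$ drives the angle ramp, which avoids a stair-cased HA
map in the ground truth.

Local frames are computed **analytically** from the ellipsoid geometry
(the radial axis is the exact shell normal), not from a fitted surface, so
the ground-truth tensors are exact: the helix angle ramps linearly from
+84° at $d_r = 0$ to −84° at $d_r = 14$, the transverse angle is 0°, and
the tensor is assembled from its eigenvector triad with eigenvalues
(2, 1.5, 1) × 10⁻³ mm²/s (so MD = 1.5 × 10⁻³ everywhere). The apex cap,
where the shell normal is parallel to the long axis and the
circumferential direction is undefined, is flagged and excluded from angle
statistics. Signals follow $S = S_0 e^{-b\, g^T D g}$ with one $b = 0$
volume plus the six-direction dual-gradient scheme at b = 350 s/mm².
$S_0 = 1$: the intensity normalization is arbitrary (scanner units are),
and none of the statistics depend on it.

## Helicoidal fiber phantom

A *synthetic* stand-in for a physical helicoidal fiber bundle: voxels in
the annulus between radii 19.08 and 27.12 mm carry a primary eigenvector
tangent to a helix around $z$, with the helix angle linear in radius from
34.57° (inner, configurable assignment) to 49.57° (outer) and zero
transverse component. The surrounding volume is an isotropic water
compartment ($D = 2\times10^{-3}$ mm²/s), emulating immersion in water;
b-values are 0 and 500 s/mm². Note a subtlety used when interpreting the
ROI mean: the *unweighted radial* mean of the ramp is the midpoint 42.07°,
while the mean over annulus **voxels** is area-weighted in radius and
evaluates to ≈ 42.5°; both are within half a degree, and the package
reports the plain voxel mean of the ROI.

## Degradation model

`simulate_lr_stacks()` degrades the ground truth per orientation
(xy, yz, xz):

1. **In-plane k-space truncation** (factor 2): per plane, 2D FFT, keep the
   centered band (for even band sizes the extra sample sits on the
   negative-frequency side), inverse FFT. For band-limited content this
   equals exact decimation; the output grid keeps the same origin.
2. **Slice selection**: the mean of 8 consecutive source planes (ideal
   rectangular profile), i.e. 8 mm slabs at 8 mm pitch.
3. **Rician noise**: $\sqrt{(S+n_1)^2 + n_2^2}$. Thick slices collect 4x
   the spins of isotropic voxels, so the SNR ratio between the
   thick-slice and native-isotropic simulations is fixed at 4; the
   absolute level is a modeling choice, set to SNR = 40 for the
   low-resolution stacks (SNR 10 for the simulated native-isotropic scan)
   as a realistic cardiac value. σ is set from the b = 0 volume
   (mean over voxels above 20% of max, divided by the target SNR) and
   shared by all diffusion channels of a stack, since thermal noise is
   channel-independent.

## Forward model and its adjoint

Each stack's acquisition operator is materialized once as a sparse matrix
(`projection_matrix()`): for every slice, in-plane sample and sub-slab
offset (one per iso-voxel width across the 8 mm slab, rectangular
weights), the world-space sample point — after the slice's rigid pose — is
expanded into its 8 trilinear interpolation weights on the iso grid.
Out-of-grid samples get weight zero (Dirichlet). The adjoint is the matrix
transpose, so the inner-product identity holds to machine precision by
construction; the tests verify it to 10⁻⁹ over random rotations up to 90°
and thickness ratios up to 8. Caching the matrix makes the per-iteration
cost of reconstruction two sparse mat-vecs per stack.

## Reconstruction solver

The objective (quadratic data terms + Beltrami) is smooth, so
`sr_reconstruct()` uses plain first-order descent: Barzilai–Borwein step
initialization safeguarded by Armijo backtracking, which keeps the
objective non-increasing and is fully deterministic. Initialization is the
adjoint-based average of the stacks normalized by a ones-image projection
(sane scaling, deterministic). Stopping: relative gradient norm ≤ 10⁻⁶ or
500 iterations. The Beltrami gradient is the discrete
$-\nabla\!\cdot\!\big(\beta^2 \nabla\rho / \sqrt{1+\beta^2|\nabla\rho|^2}\big)$
consistent with the forward-difference energy (verified against finite
differences to 10⁻⁶); because the +1 under the root already smooths the
functional at zero gradient, the extra smoothing constant defaults to 0
and exists only for total-variation-mode experiments. Diffusion channels
are reconstructed independently (the operators are shared and cached);
there is no joint tensor-space coupling.

With $S_0 = 1$, $\lambda = 10^{-5}$ is numerically inert: the regularizer
gradient is bounded by $\lambda\beta$, orders of magnitude below the data
gradient at any realistic noise level — and the same holds at scanner
intensity scales. The reconstruction behaves as a fully converged least
squares; consequences are discussed under *Limitations*.

## Slice-to-stack registration

Each slice's 6-parameter rigid pose (intrinsic Z–Y–X rotations about the
slice center, then world translation; the center pivot decouples rotation
from translation) is estimated by maximizing the sum over target slices of
the Pearson correlation between intensity profiles sampled along the
slices' intersection lines, clipped to both fields of view and to the
shared region Ω, with linear interpolation. Profiles from all diffusion
channels (including b = 0) are standardized per channel and concatenated
into a single correlation per slice pair; short (< 8 samples) or constant
profiles are skipped.

Three robustness choices matter and are the package's own:

* **Matched-blur profiles.** A thick floating slice and a thick target
  slice see the object through different slab footprints; raw profiles
  then correlate below 1 even at perfect alignment, and the residual
  mismatch can pull the optimizer toward tilted poses. Each profile is
  therefore blurred with the *partner* slice's slab footprint (a
  rectangular average along the in-plane projection of the partner's
  normal), after which two aligned noiseless slices yield identical
  profiles up to interpolation and the similarity peaks at the true pose.
* **Frozen term sets.** The plain sum of correlations rewards poses that
  merely acquire additional valid intersection terms (an empty edge slice
  can "gain" a unit of similarity by sliding into the object). During one
  slice's optimization the set of valid terms is frozen at its current
  pose.
* **Evidence-thresholded coordinate descent.** The per-slice search is a
  bounded coordinate descent (Brent line searches over shrinking brackets,
  translations first), and a move is only accepted if it improves the
  similarity beyond a threshold (10⁻³ for translations, 5 × 10⁻² for
  rotations). The rotation threshold is deliberately coarse: at 8 mm slab
  thickness, in-bounds rotations of smooth anatomy change the similarity
  by about as much as the interpolation ripple, so without clear evidence
  a slice keeps its prior orientation. A multi-start fallback (±half the
  translation bounds) triggers only when the local search neither improved
  nor reached a good mean correlation.

Sweeps are Gauss–Seidel: every slice of stack 1 is optimized and applied
immediately, then stacks 2 and 3, repeated (default five outer sweeps; the
pose changes are negligible after the first two or three). Registered
poses enter the reconstruction through the projection matrices.

At the simulated study conditions (64 × 64 × 48 phantom, noiseless,
translation-dominant planted motion — |trans| ≤ 4 mm, |rot| ≤ 1°, 30% of
object-overlapping slices, reflecting that inter-breath-hold motion is
predominantly translational), planted translations are recovered with
median error below 1 mm (isolated slices: below 0.2 mm) and poses respect
the search bounds. Rotations of this magnitude are at the identifiability
floor of the metric for this smooth phantom and are intentionally left
near the prior.

## Tensor fitting and scalar maps

`dti_fit()` solves the log-linear system per voxel (design matrix over
$\ln S_0$ and the six tensor components; signals clamped at
$10^{-6} S_0$ before the log). With the dual-gradient scheme plus one
b = 0 the system is exactly determined and noiseless data are recovered to
round-off; a one-pass weighted refit (weights = squared fitted signals) is
available as `method = "wls"`. Eigen-decomposition orders eigenvalues
descending and fixes the sign of each eigenvector deterministically;
helix/transverse angles are antipodally invariant, so the sign convention
never leaks into the maps. MD is trace/3; FA uses the standard normalized
eigenvalue dispersion and is defined as 0 for a zero tensor.
Non-positive-definite voxels are flagged, never silently repaired.

## Cardiac frames and angles

For phantom work the frames are analytic. For segmentation-style input,
`fit_lv_surface()` builds a smooth implicit surface from sparse planar
contours by triharmonic radial-basis interpolation ($\phi(r) = r^3$ plus a
linear polynomial) of a signed pseudo-distance: contour points carry 0,
and off-surface points offset ±2 mm along in-plane outward normals carry
±2. This replaces a published implicit B-spline reconstruction whose
details are not available; the contract — a smooth implicit field with a
usable gradient — is the same. A dimensionless ridge (`lambda_smooth`)
trades interpolation for smoothness with noisy contours. The local triad
is `er` = normalized field gradient, `ec` = long-axis × `er` (normalized),
`el` = `er` × `ec`; apex-cap points where the gradient is parallel to the
long axis are flagged and excluded from angle statistics, as are voxels
gated out by FA ≤ 0.05 (configurable), where the eigenvector direction is
unstable.

Angles (after folding the ±e₁ ambiguity so the circumferential component
is non-negative): HA = atan2(e₁·el, e₁·ec) ∈ [−90°, 90°], positive for a
right-handed helix at the endocardium (matching the +84° endocardial
specification of the phantom); TA = atan2(e₁·er, |tangent projection|).

## Analysis conventions

* Eroded-mask statistics use a one-voxel, 6-connected erosion at analysis
  resolution to suppress partial-volume boundary voxels; the amount is
  configurable and reported in every summary.
* Transmural profiles pool voxels into five equal wall-depth layers
  ([0,20)…[80,100] percent) and fit the HA slope in °/% by ordinary least
  squares over all voxels (Theil–Sen optional). The ±84° ramp therefore
  has slope −1.68 °/%.
* The global MAE equals the voxel-count-weighted mean of the per-slice MAE
  curve (tested identity).
* ROI SNR = mean(signal ROI) / SD(background ROI). When a native stack is
  compared with the reconstruction on the same grid it is reformatted by
  nearest-slab replication, which preserves the stack's own noise
  statistics (through-plane linear interpolation would deflate its
  background SD and flatter the comparison in either direction).

## Problem sizes used by the tests

The acceptance-level tests scale the phantom to 96 × 96 × 80 voxels with
$R_{max} = 48$, preserving $R_{min} = 16$ and the 14-voxel wall range (so
wall physics and the HA ramp are untouched; only the long axis shortens);
reconstruction runs at 2 mm on 48 × 48 × 40. Registration experiments use
a 64 × 64 × 48 phantom with three outer sweeps, where the estimated poses
have already stabilized. Unit tests use a 48 × 48 × 40 phantom with
proportionally reduced radii.

## What the synthetic experiments do and do not show

The phantoms share the piecewise-smooth, high-contrast, rotationally
symmetric character of segmented anatomy but none of the texture, B0/B1
inhomogeneity, EPI distortion, eddy currents, perfusion or residual
cardiac motion of real scans. Passing tests demonstrate that the
operators, the solver, the registration machinery and the angle
conventions are internally consistent and that the reconstruction is
unbiased for MD and HA under the stated degradation model — not that the
method is validated on scanner data.

Known limitations, measured and documented rather than hidden:

* **LR diffusivity bias is noise-level dependent.** The small MD
  underestimation expected of thick-slice data is a Rician noise-floor
  effect scaling with σ²; at SNR 40 it is ~0.1%, far below the few-percent
  seen at lower SNR.
* **Fully converged least squares amplifies background noise.** With the
  inert $\lambda = 10^{-5}$, the exact inversion of the 4× slab average
  raises the background SD by ~1.5× over a native stack, so the
  reconstruction's background-ROI SNR is *lower* than a native stack's
  even though the myocardial signal is restored. A practical deployment
  would either raise λ by several orders of magnitude or stop the solver
  early; both are exposed (`lambda_reg`, `max_iters`) but the defaults keep the
  values stated above.
* **Per-slice rotations are weakly identifiable** from intersection
  profiles of smooth objects at 8 mm slab thickness; the optimizer
  therefore demands strong evidence before rotating a slice.
* The apex cap is excluded from all angle statistics (frames degenerate
  there), and slices whose slabs do not overlap the object cannot be
  registered (they are detected and left at their prior pose).
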