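# srcdti

Super-resolution reconstruction and myofiber-architecture analysis for
cardiac diffusion tensor MRI (cDTI), in R.

Cardiac DTI maps the water diffusion tensor in the beating myocardium, and
from its primary eigenvector the helical organization of cardiomyocytes:
the **helix angle** (HA), which ramps from strongly positive at the
endocardium to strongly negative at the epicardium, and the **transverse
angle** (TA). In-vivo acquisitions are constrained to thick slices
(typically 2 × 2 × 8 mm³), which blurs exactly the transmural structure of
interest. One remedy is to acquire **three orthogonal stacks of thick
slices** and to combine them into one isotropic volume by solving the
regularized inverse problem

```
argmin_ρ  Σᵢ ‖ Dᵢ Bᵢ Tᵢ ρ − ρᵢ ‖²  +  λ Q(ρ),      Q(ρ) = Σ √(1 + β²|∇ρ|²)
```

where `Tᵢ` resamples the isotropic volume `ρ` into stack *i*'s frame, `Bᵢ`
is the through-plane slice profile, `Dᵢ` the slice down-sampling, `ρᵢ` the
measured stack, and `Q` the Beltrami energy (a smooth, edge-preserving
relative of total variation; defaults λ = 10⁻⁵, β = 1). Because each slice
is acquired in a separate breath-hold, the package first corrects
inter-slice motion by **slice-to-stack registration**: each slice's rigid
pose is optimized (bounded, rotations < 5°, translations < 8 mm) to
maximize the summed correlation of intensity profiles along its
intersection lines with the slices of the other stacks.

The package is aimed at researchers developing or validating cDTI
post-processing: it contains everything needed to run the full analysis
on synthetic data end to end —

* **Phantoms** — a semi-ellipsoid left-ventricle phantom with a linear
  transmural HA ramp (+84° endo → −84° epi, TA = 0°, eigenvalues
  (2, 1.5, 1)×10⁻³ mm²/s) and a helicoidal fiber-bundle phantom whose HA
  ramps over the bundle radius (34.57°–49.57°, midpoint 42.07°).
* **Degradation** — in-plane k-space truncation, rectangular slice
  selection, Rician noise at a target SNR.
* **Forward model** — the acquisition operators as cached sparse matrices
  with exact adjoints (`forward_project()`, `adjoint_project()`).
* **Reconstruction** — `sr_reconstruct()` / `sr_reconstruct_dwi()`,
  Barzilai–Borwein gradient descent with Armijo backtracking.
* **Registration** — `register_slice()`, `register_stacks()`.
* **Tensor fitting** — `dti_fit()` (log-linear least squares), eigen
  system, MD, FA.
* **Cardiac frames and angles** — implicit-surface fitting from sparse
  contours, local (radial, circumferential, longitudinal) frames,
  `helix_transverse_angles()`.
* **Analysis** — eroded-mask statistics, Bland–Altman, MAE-by-slice
  curves, five-layer transmural profiles with the HA slope, ROI SNR.

A thin command-line wrapper is installed at `inst/cli/srcdti`
(subcommands `simulate`, `degrade`, `reconstruct`, `fit`, `run`).

## Worked example

```r
library(srcdti)

spec <- lv_phantom_spec(grid_dim = c(64, 64, 48), r_min = 12,
                        r_max = 26, wall = 10)
ph     <- lv_phantom(spec)
gt     <- synthesize_dwi(ph$tensors, dual_gradient_scheme(350),
                         ph$mask, ph$grid)
stacks <- simulate_lr_stacks(gt, degradation_spec(snr = 40, seed = 7))
rgrid  <- iso_grid(gt$grid$dim %/% 2, spacing = 2)
sr     <- sr_reconstruct_dwi(stacks, rgrid, sr_config())
# myocardial wall mask evaluated on the reconstruction grid
wall   <- lv_reference_on_grid(spec, rgrid)$mask
fit    <- dti_fit(sr, mask = wall)
summary(fit)
```

```
dti_fit summary (ols, 3502 voxels)
  MD 0.001506 +/- 0.00011 mm^2/s; FA 0.356 +/- 0.075; SPD 100.0%
```

The mean MD of the wall after the full degrade → reconstruct → refit chain
is 1.51 ×10⁻³ mm²/s against the generator's 1.50 ×10⁻³ (trace of the
(2, 1.5, 1)×10⁻³ tensor / 3): the super-resolution reconstruction does not
bias the diffusivity; eroding the mask by one voxel
(`eroded_mask_stats()`) gives 1.501 ± 0.095 ×10⁻³ mm²/s at this noise
level. Recomputing HA from the
fitted first eigenvectors in the analytic frames reproduces the generator
ramp, and `transmural_profile()` on the ±84° ramp returns a slope of
−1.68 °/% wall depth.

`run_pipeline(pipeline_config(), out_dir)` chains all stages (simulate →
degrade → register → reconstruct → fit → angles → report) and writes
NIfTI volumes, a resolved YAML config, `report.json` and a manifest with
MD5 hashes.

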