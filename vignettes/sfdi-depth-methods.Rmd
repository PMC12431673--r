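---
title: "Methods: simulated SFDI and learned subsurface fluorescence depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated SFDI and learned subsurface fluorescence depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(SFDIdepth)
```

## The problem

In oral cancer surgery the decisive quantity at the deep resection surface
is the closest margin distance: how far beneath the specimen surface the
tumor sits (<1 mm positive, 1–5 mm close, >5 mm clear). Wide-field
fluorescence imaging sees tumor-targeted fluorophores such as
protoporphyrin IX (PpIX) but ordinarily cannot say how deep they are.
Spatial frequency domain imaging (SFDI) adds that missing axis: tissue is
illuminated with sinusoidal patterns at several spatial frequencies, and
because high-frequency patterns wash out within a shallow depth while DC
illumination penetrates deep, the decay of the demodulated fluorescence
across frequency encodes the depth of a buried fluorescent inclusion.

`SFDIdepth` implements the full computational pipeline around that idea:

1. **Scene synthesis** — randomized composite-spherical-harmonic (CSH)
   tumor shapes buried in homogeneous tissue, or voxelized patient-style
   triangle meshes.
2. **Forward model** — a finite-difference diffusion solver producing
   diffuse reflectance and diffuse fluorescence images at each spatial
   frequency.
3. **Optical-property recovery** — three-phase demodulation, reference
   calibration, and two-frequency lookup-table (LUT) inversion giving
   per-pixel absorption and reduced-scattering maps.
4. **Dense regression** — two convolutional architectures (a Siamese
   ResNet and an attention U-Net) mapping the six-frequency fluorescence
   stack plus the two optical-property maps to per-pixel margin distance
   (mm) and fluorophore concentration (µg/ml).
5. **Evaluation** — masked MAE ± SD, depth-binned MAE, closest-depth
   error, equality-line R², and independent t-tests between models.

## Light propagation model

The solver discretizes the steady-state diffusion equation on the scene
voxel grid. Patterned illumination at spatial frequency $f_x$ is handled
in the standard SFD way, as an effective absorption:

$$-\nabla\cdot(D\nabla\varphi) + \big(\mu_a + (2\pi f_x)^2 D\big)\varphi = S,
\qquad D = \frac{1}{3(\mu_a+\mu_s')},$$

so the modulation envelope decays with the effective attenuation
$\mu_\mathrm{eff}'(f_x)=\sqrt{3\mu_a(\mu_a+\mu_s') + (2\pi f_x)^2}$. The
collimated source is reduced to a plane source buried at one transport
mean free path $1/(\mu_a+\mu_s')$; the top surface carries a Robin
(partial-current) boundary with internal-reflection parameter $A \approx
3.25$ for tissue refractive index $n = 1.4$; lateral and bottom faces are
zero-flux, pushed ≥ 10 mm away from the field of view by background
padding. Fluorescence emission uses a second solve at the same frequency
with source $q = \eta\,\gamma\,C(\mathbf r)\,\varphi_x(\mathbf r)$, with
quantum efficiency $\eta = 0.046$ and a concentration-to-absorption
constant $\gamma = 10^{-5}\,\mathrm{mm^{-1}}$ per µg/ml, small enough that
the fluorophore never perturbs $\mu_a$ — which keeps the fluorescence
stack exactly linear in the concentration field, a property the test
suite asserts. Emission optical properties default to the excitation
values (single-wavelength simulation at the 630 nm excitation band).

Two backends share the identical 7-point discretization:

* a spectral path for homogeneous coefficients — lateral Neumann modes via
  a mirrored FFT, one tridiagonal solve in depth per mode (C++); and
* a sparse-Cholesky path for per-voxel coefficients.

Their agreement on homogeneous problems is asserted at $10^{-8}$ relative.

**Closed-form oracle.** For a homogeneous half-space the same model has a
closed form: with $\mu' = \mu_\mathrm{eff}'(f_x)$, $z_0 = 1/\mu_t'$ and
$\Gamma = (1-2AD\mu')/(1+2AD\mu')$,

$$R_d(f_x) = \frac{e^{-\mu' z_0}\,(1-\Gamma)}{4\,A\,D\,\mu'}.$$

This expression is derived independently of the solver and frozen into
the tests; the numerical reflectance must match it to 2 % at all six
frequencies over the whole training range of optical properties.

**Depth step.** A one-dimensional discretization study (comparing the
finite-difference solution against the closed form) showed the relative
error at $f_x = 0.25\,\mathrm{mm^{-1}}$ is ≈ 10 % at a 0.5 mm depth step,
≈ 2.5 % at 0.25 mm and ≤ 0.7 % at 0.125 mm across the training optical
properties. The solver therefore refines the scene's 0.5 mm depth pitch
by 4 by default (`zrefine = 4`); dataset generation for network training
uses `zrefine = 2`, where the residual high-frequency bias is shared
identically by training and test scenes and so does not affect learning.

## Synthetic tumor shapes

Each CSH shape merges (voxel-space union) four star-convex bodies
$r(\theta,\phi) = r_0\,(1 + a\,\bar Y_{l m}(\theta,\phi))$ with the
harmonic scaled so $\max|\bar Y| = 1$. Degree $l$ is drawn uniformly from
{2…6} and order $m$ uniformly from {2…l}, satisfying both the stated 2–6
range and $|m| \le l$; a random cos/sin form and phase are applied. The
perturbation amplitude $a$ is drawn from [0.1, 0.5] — bounded below 1 so
the radius stays positive (the merging operator and the amplitude range
are design choices; the union is the simplest operator producing
irregular composite topographies). Components receive random lateral
offsets (|offset| ≤ 0.7 in unit space) and the union is resampled until
6-connected. The merged body is anisotropically rescaled so its maximum
lateral extent equals the sampled width (5–40 mm) and its axial extent
the sampled height (5–10 mm) — extents measured analytically on the
component surfaces, so the voxelized shape respects the intervals up to
one voxel pitch — then translated so the shallowest voxel sits at the
sampled top depth (1–10 mm). Width and height are read as bounding-box
extents, the way a surgeon-facing measurement would be.

Scenes assign homogeneous optics per case: $\mu_a \in [0.0015, 0.015]$,
$\mu_s' \in [0.75, 2]\,\mathrm{mm^{-1}}$ (or the low-scattering
alternative $\mu_a \in [0.01, 0.3]$, $\mu_s' \in [0.3, 0.7]$), tumor PpIX
1–10 µg/ml, and background fluorescence at 0.1–50 % of the tumor value.
Ground truth assigns each pixel the depth of the top face of the
shallowest tumor voxel in its column and exactly 10 mm to tumor-free
columns, so the map minimum always belongs to the tumor body; the
concentration map carries the tumor value over every tumor-intersecting
column.

What the generator does **not** emulate: heterogeneous intratumoral
optics, fluorophore leakage and peripheral accumulation, non-flat surface
topography, instrument noise, and container-wall reflections. Passing
tests therefore demonstrate correctness of the simulation-training-
evaluation loop under diffusion-theory physics, not performance on real
specimens.

## Optical-property recovery

Demodulation is the exact three-phase formula
$AC = \tfrac{\sqrt2}{3}\sqrt{(I_1-I_2)^2+(I_2-I_3)^2+(I_3-I_1)^2}$.
Calibration is single-reference and per-pixel (dark-frame subtraction
assumed upstream). The LUT tabulates closed-form $R_d$ pairs at
$f_x = 0$ and $0.2\,\mathrm{mm^{-1}}$ on a 64 × 64 grid over the training
ranges; inversion minimizes the Euclidean distance in reflectance space
with each axis normalized by its dynamic range (the two frequencies
differ in scale), refines below the node spacing with a bilinear sub-grid
search, clamps out-of-gamut pixels to the boundary and flags them, and
breaks exact ties toward lower $\mu_a$, then lower $\mu_s'$. Whether the
original processing interpolated or used nearest nodes is not
documented; interpolation was chosen because the node-exactness and
round-trip contracts hold either way and interpolation removes the
quantization floor. The LUT uses the closed form rather than the
numerical solver because the two agree within the oracle tolerance.

## Architectures

Both variants share the input contract — a $(6, H, W)$ fluorescence
stack processed by 3 × 3 × 3 convolutions over $(f_x, x, y)$ and an
$(H, W, 2)$ optical-property pair processed by 3 × 3 convolutions — and
the output contract of two full-resolution linear 1 × 1 heads (depth,
concentration). Every other convolution is followed by ReLU; when
dropout is enabled (rate 0.2, a common convolutional setting; the
original rate is unstated) a dropout layer follows each branch
convolution before concatenation.

* **ResNet** (2,000,642 parameters): residual blocks with identity
  shortcuts before and after branch concatenation, constant lateral
  resolution. Default widths: 16 (3D branch), 182 (frequency-collapse),
  52 (optics branch), 138 (trunk), 64 (heads).
* **Attention U-Net** (33,145,143 parameters): max-pooling encoder over
  widths 64/128/256/512 with a 1064-channel bottleneck, nearest-neighbour
  upsampling, and additive attention gates (1 × 1 convolutions
  $W_g$ with bias, $W_x$ without, $\psi$ to a sigmoid coefficient in
  [0, 1] multiplying the skip features) with inner widths 256/128/65/53
  from coarsest to finest.

Only the two parameter totals are hard architectural constraints from the
reference description; layer counts and widths were fixed by integer
search so the defaults reproduce those totals exactly, which the test
suite asserts. The engine (im2col convolutions, pooling, upsampling,
attention, Adam) is implemented in C++/R and its gradients are verified
against finite differences.

## Training and evaluation choices

The original loss, optimizer, split and schedule are unstated; the
package defaults use: full-image L1 on both maps with the targets scaled
to comparable ranges (depth / 15 mm — the full extent of the binned
evaluation — and concentration / 10 µg/ml), Adam at $10^{-3}$ with an
optional step decay, batch 16, a 90/10 split, and the best-validation
checkpoint. L1 aligns the training objective with the reported MAE
metric. The loss is evaluated over the whole image rather than tumor
pixels only because the closest-depth metric takes the minimum over the
*entire* predicted map: the network must learn the 10 mm background
convention or a single low background pixel would corrupt the clinical
quantity. The default input normalization divides the fluorescence stack
by its per-scene $f_x = 0$ maximum (removing the arbitrary source
normalization while preserving the cross-frequency decay that encodes
depth) and min–max scales the optical maps by the training ranges.

Two refinements, exposed as options and used by the scaled study, came
out of a failure analysis of that default configuration:

* **Log-contrast fluorescence representation**
  (`normalizationScheme(fluorNorm = "log-contrast")`). After scene-max
  scaling, the high-frequency channels are numerically tiny
  ($10^{-4}$–$10^{-6}$): a ReLU network effectively cannot see them and
  falls back on the low-frequency bump contrast, which confounds depth
  with tumor width. A pure log map equalizes channel magnitudes but
  compresses the spatial contrast that localizes the inclusion. The
  log-contrast form keeps both cues: each frequency image is normalized
  to its own maximum (full spatial contrast in every channel) and
  rescaled by $1 + \log_{10}(\max_k/\max_0)/7$, so each channel's overall
  brightness carries the log-domain amplitude decay — the physical depth
  cue, which is linear in depth in the log domain
  ($\log F_k \sim -\mu_\mathrm{eff}'(f_{x,k})\, d$).
* **Tumor-pixel weighting** (`trainConfig(tumorWeight = 8)`). The
  smallest admissible tumors (5 mm wide) occupy a few pixels of the
  scaled image, contributing on the order of 1 % of a uniform L1 loss;
  the optimizer rationally ignores them, which is fatal for a metric
  defined by the map minimum. Weighting tumor-column pixels eight-fold
  (and down-weighting the concentration term to 0.25) keeps the loss
  aligned with the clinically decisive region while the background
  convention is still learned.

Evaluation restricts per-pixel errors to tumor columns, bins them by true
depth (0–5, 5–10, 10–15 mm), and reports the closest-depth error
$|\min \hat d - \min d|$ per case. R² is computed about the line of
equality, $1 - \sum(\hat y_i - y_i)^2 / \sum(y_i - \bar y)^2$ — not
about a fitted line — because the quantity of interest is agreement with
the truth, and this definition can legitimately be negative for
predictions worse than the mean. Model comparisons use the two-sided
independent t-test with equal variances and the conventional star
thresholds.

## Scaled study conditions

The full-scale corpus (10,000 scenes at 101 × 101 px, hours of
simulation and GPU training) is intentionally out of desk scale. The
package's self-contained parameter-recovery study instead uses: 25 × 25
px at 2 mm/px (50 mm field, still covering the 5–40 mm widths), 0.5 mm
depth pitch, solver `zrefine = 2`, 500 training scenes with the full
randomized optics, and 40 held-out CSH scenes at the fixed test
properties ($\mu_a = 0.0045$, $\mu_s' = 1\,\mathrm{mm^{-1}}$, 5 µg/ml,
randomized background fraction). The network is a width-scaled attention
U-Net (two encoder levels, ≈ 130 k parameters) trained for 40 epochs
with the log-contrast representation, tumor-pixel weighting 8,
concentration weight 0.25 and learning-rate decay at epochs 25 and 35.
Under these conditions the held-out closest-depth MAE is required to stay
below 1.0 mm — a deliberately relaxed bound consistent with sub-half-mm
accuracy at full scale, chosen once for the scaled conditions. Shape
property checks run on 15 reduced-grid seeds plus one full-resolution
seed — large enough to catch range violations, small enough for a
routine test run.

## Numerical details and degenerate inputs

* Solver tolerance: the spectral path is direct (FFT + tridiagonal), the
  sparse path a direct Cholesky solve — no iteration, bitwise
  reproducible.
* Degenerate optics intervals (min = max) produce deterministic scenes;
  degenerate LUTs (no reflectance dynamic range) are rejected rather
  than silently inverted, and dataset generation always builds its LUT
  over the full training domain even when the scene optics are fixed.
* Masks that would touch the $z = 0$ surface are invalid: the inclusion
  must be buried.
* All quantities are carried in mm, mm⁻¹ and µg/ml; image axes are
  (row = y, col = x), depth increases into the tissue, voxel centers at
  $(i-\tfrac12)\cdot$pitch.
* One master seed spawns per-record child seeds
  ($\mathrm{seed}\cdot 1000003 + i \bmod 2^{31}-1$), making dataset
  generation reproducible and resumable per record.

## Known limitations

Diffusion theory assumes scattering dominates absorption; the
low-scattering range flirts with that limit and the simulated images
there should be read accordingly. The concentration head is weakly
constrained after per-scene normalization (only the background fraction
and optics pin the absolute scale), mirroring the larger concentration
errors reported for this class of system. Mesh voxelization assumes
watertight, axis-oriented meshes with the deep surface facing the
imaging plane.
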