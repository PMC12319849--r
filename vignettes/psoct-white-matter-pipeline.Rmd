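---
title: "Mapping white matter with PSOCT: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping white matter with PSOCT: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoctr)
```

## The measurement problem

Polarization-sensitive optical coherence tomography (PSOCT) images tissue
with two orthogonal polarization detection channels, each delivering a
complex depth profile $A_{1,2}(z)\,e^{i\phi_{1,2}(z)}$ per lateral position.
In white matter, the lipid-ordered myelin sheath is birefringent with its
optic axis parallel to the axons, so three optical properties carry
anatomical meaning:

* **reflectivity** $R(z) \propto A_1^2 + A_2^2$, the backscattered
  intensity;
* **retardance** $\delta(z) = \arctan(A_1/A_2)$, the cumulative phase delay
  between polarization eigenstates, rising with myelin content and falling
  where fibers cross or dive through the imaging plane;
* **optic-axis orientation** $\theta(z) = [\phi_1(z) - \phi_2(z)]/2$, the
  in-plane fiber direction, a *axial* (180°-periodic) quantity.

A fourth map, the scattering coefficient $\mu_s$, is estimated depth-resolved
from the reflectivity because near-infrared attenuation in brain tissue is
scattering-dominated:

$$\mu_s(z) = \frac{I(z)}{2\,\Delta \sum_{j=z+1}^{d} I(j)}$$

with $I$ the linear reflectivity signal, $\Delta$ the axial pixel size and
$d$ the imaging depth. Both $\mu_s$ and birefringence track myelin, which
makes these maps a micrometer-scale readout of myelination — and directly
comparable, after co-registration, with diffusion-MRI ADC and FA maps of
the same tissue.

This package implements the full chain — simulation, reconstruction,
en-face mosaicking, 2D tractography, cross-modal registration, ROI
statistics — with a synthetic birefringent phantom standing in for
postmortem specimens, so that every stage has a known recovery target.

## The phantom forward model

`simulate_ascan()` / `simulate_volume()` generate dual-channel complex
A-lines from voxel maps of $\mu_s$ (mm⁻¹), birefringence $\Delta n$, and
fiber axis $\theta$:

* **Amplitude.** Single-backscatter with
  $A(z) = \sqrt{\beta\,\mu_s(z)}\;\exp\!\big(-\sum_{j\le z}\mu_s(j)\Delta\big)$,
  so the detected intensity decays with the double-pass attenuation that
  the $\mu_s$ estimator inverts. The backscatter fraction $\beta$ is a
  fixed configurable constant (default 0.01); no multiple scattering,
  speckle, diattenuation or depolarization is modeled. The model is
  sufficient for recovery testing, not a radiometric simulation.
* **Polarization.** Each pixel is a linear retarder
  $R(\theta_k)\,\mathrm{diag}(e^{i\delta_k}, e^{-i\delta_k})\,R(-\theta_k)$
  with $\delta_k = (2\pi/\lambda)\,\Delta n_k\,\Delta$; the cumulative
  single-pass Jones matrix is the ordered product and the reflection round
  trip is the transpose product $M = J^\top J$. Detection uses circular
  input polarization; the co- and cross-polarized circular components are
  the two channels (with a quarter-wave bias on the cross channel). For a
  uniform-axis medium this makes the estimators exact:
  $\arctan(A_1/A_2)$ equals the folded cumulative **double-pass**
  retardance $2\,(2\pi/\lambda)\,\Delta n\,z$ and $(\phi_1-\phi_2)/2$
  equals $\theta$. In layered media with varying axis the Jones product is
  still exact but the estimates become "apparent" values; exact-recovery
  tests therefore use uniform-axis phantoms.
* **Through-plane fibers.** `through_plane_deg` scales apparent
  birefringence by $\cos^2$ of the inclination, reproducing the
  low-retardance appearance of tracts diving through the section.
* **Noise.** Additive circular complex Gaussian noise per channel, drawn
  from one stream in a documented order (per A-line, channel 1 first,
  real parts then imaginary parts), so identical (spec, noise, seed)
  triples give bit-identical volumes.

A quarter-wave caveat worth knowing: once the cumulative double-pass
retardance exceeds 90°, the co-polarized channel changes sign, which shifts
the channel phase difference by 180° and flips the estimated axis by 90°.
This is a property of the $(\phi_1-\phi_2)/2$ estimator itself, not of the
simulator; with developmental-brain birefringence ($\Delta n \le 5\times
10^{-4}$) and 100–170 µm slices the ambiguity is never reached. The
retardance fold at 90° (triangle-wave wrapping) is handled explicitly and
tested against the closed form.

The matched dMRI stand-in (`simulate_dmri_maps()`) builds, per coarse voxel
(default 0.8 mm), the mixture of prolate diffusion tensors aligned to the
local 3D fiber axes plus isotropic background tensors, and reports ADC
(mean diffusivity), FA, and the leading eigenvector. Mixed-orientation
voxels get lower FA than coherent ones, the familiar crossing-fiber
behavior of the tensor model. Diffusivities are explicit parameters
(defaults: axial 1.2×10⁻³, radial 3×10⁻⁴, background 0.8×10⁻³ mm²/s,
ex-vivo-like); in the developmental series the radial diffusivity falls
with myelination, which is what drives ADC down and FA up.

What the generator does **not** emulate: spectrometer physics
(k-linearization, dispersion, sensitivity roll-off), speckle statistics,
multiple scattering, Mueller-matrix depolarization, tissue deformation, and
scanner noise in the diffusion maps. Passing tests therefore demonstrate
the correctness of the estimators and the pipeline plumbing under the
stated forward model — not robustness to every artifact of real
acquisitions.

## Reconstruction choices

* `fourier_reconstruct()` removes DC by per-spectrum mean subtraction and
  keeps the positive-frequency half of the inverse DFT — the minimal,
  reproducible spectral-domain reconstruction. `synthesize_fringes()` is
  its exact inverse, used to validate the round trip to $10^{-9}$ relative
  error.
* $I$ in the $\mu_s$ formula is the **linear** reflectivity (not dB): the
  estimator's derivation requires linear intensities.
* The finite tail sum is implemented exactly as written. Its known
  consequence is a positive bias that grows toward the bottom of the
  profile, because signal that would have been collected below depth $d$
  is missing from the denominator; the bias is negligible while
  $2\mu_s\Delta\,(d-z) \gtrsim 3.5$ and is why tests assert 5% accuracy
  over the first half of sufficiently deep profiles only. On shallow
  desk-scale phantoms (40 pixels ≈ 170 µm) the en-face $\mu_s$ is
  inflated by this bias; it remains strictly monotone in the true
  $\mu_s$, which is what the correlation analyses rely on. A
  `tail_drop` parameter removes the worst trailing pixels from the maps.
* Retardance is folded into [0°, 90°] by construction; axis angles live in
  [0°, 180°) everywhere in the package, with NaN for invalid pixels. The
  SNR floor for axis validity defaults to 0 (mask nothing); with noisy
  data a floor of ~3× the channel noise SD is sensible, since orientation
  noise is inversely related to signal SNR.
* Empty tail sums (last pixel, or all-zero tails) give NaN rather than a
  guess.

## En-face maps, stitching, stacking

Scalar volumes collapse to en-face maps by NaN-ignoring depth means.
Orientation uses the field's convention: a histogram of valid angles in 5°
bins, reporting the center of the fullest bin (ties to the lowest bin, for
determinism). The estimator is therefore bin-quantized: a coherent bundle
at 30° reports 32.5°, and ROI-level checks use a ±2.5° tolerance.

Tiles (20% overlap, offsets from the stage) are fused by linear blending:
per-tile weights ramp linearly across the overlap width and are normalized
to sum to one wherever at least one tile contributes. Orientation maps are
blended on doubled-angle unit vectors and halved back — naive averaging
would turn 178° and 2° into 90° instead of 0°. Nominal offsets are trusted
by default (blockface acquisition has exact stage coordinates); an optional
±5 px phase-correlation refinement exists for data with stage drift.
Sections stack by plain concatenation with recorded slice thickness
(100–150 µm): blockface geometry needs no inter-slice registration.

## Tractography

`track()` is a FACT-style streamline tracker native to 2D axial fields: at
each Euler step (default 0.5 px) the direction is the nearest pixel's
orientation, with the sign chosen to continue the previous step — axial
data has no intrinsic sign, so each seed spawns both signs, one per
half-track. Termination follows the published rules: leaving the
retardance-derived white-matter mask, an axial angle change above 45°
between consecutive pixels, NaN orientation, or the length cap. The
retardance threshold for the mask is Otsu's method by default, since no
fixed value generalizes across myelination stages. An optional
doubled-angle bilinear interpolation mode improves accuracy on smooth
fields (circular-arc following drifts ~1.5% in radius per revolution at a
0.25 px step, measured by the package's own convergence test). Seed points
come from a regular grid intersected with the mask (default every 5–10 px);
seeds outside the mask are skipped with a warning rather than an error.

## Cross-modal registration

`register_affine()` maximizes normalized cross-correlation between the
fixed scattering map and the (negated, since ADC and $\mu_s$ are
anti-correlated in white matter) moving ADC map, over a 6-parameter affine
(rotation, two log-scales, shear, translation), coarse-to-fine over an
image pyramid, initialized by center-of-mass alignment and the pixel-size
ratio. An affine is sufficient because blockface acquisition has no
nonlinear distortion; nothing deformable is attempted. The rotational
component — applied to diffusion vectors before in-plane projection — is
extracted by polar decomposition (unique, with a symmetric positive
remainder; QR would mix shear into the rotation). Vectors whose in-plane
projection is shorter than 0.1 are through-plane fibers and flagged
invalid rather than assigned a meaningless 2D angle. Registration quality
is evaluated with Dice overlap of tissue and white-matter masks; two empty
masks define Dice = 1 so degenerate fixtures do not produce NaN.

## ROI statistics

ROIs are 0.9 × 0.9 mm boxes on a regular lattice, kept when their
white-matter fraction reaches 0.8 and thinned deterministically to the
requested count — a reproducible replacement for manual ROI selection.
Per ROI the package reports NaN-ignoring means of $\mu_s$, retardance, ADC
and FA, and axial circular means of both orientation sources (angles
doubled, resultant vector averaged, argument halved; a near-zero resultant
is flagged degenerate and returns NaN). Orientation agreement uses the
polar-space difference $\min(|a-b| \bmod 180,\ 180 - |a-b| \bmod 180)$, so
178° and 1° differ by 3°, never 177°. Whole-white-matter summaries use the
population standard deviation by default (configurable). Correlations are
plain Pearson coefficients after pairwise NaN deletion, with constant or
too-short input rejected loudly; no significance testing is attempted.

## The developmental age series

`age_series_conditions()` fixes the synthetic stand-ins for five specimens
spanning 3–54 months: white-matter $\mu_s$ = 1.2, 2.0, 4.0, 8.0, 10.0 mm⁻¹
(a near-tenfold rise over the first years, ending around 80% of adult
white-matter values), $\Delta n$ rising 1×10⁻⁴ → 5×10⁻⁴, and radial
diffusivity falling 6.5×10⁻⁴ → 3.3×10⁻⁴ mm²/s. Each age is a two-bundle
phantom (axes 30° and 150°) on a 6 × 6 mm section sampled at 30 µm
laterally × 4.2 µm axially × 40 depth pixels, with channel noise SD 0.005;
24 ROIs per age give 120 pooled ROIs. These sizes keep the whole series
under a minute of computation while leaving every estimator in its tested
regime. `simulate_age_series()` runs the chain and pools ROI tables; the
signs of the pooled correlations (negative $\mu_s$–ADC, positive
retardance–FA) are the recoverable content at this scale — correlation
magnitudes from physical specimens depend on biological variability that
the phantom deliberately lacks, and are not targets.

## Conventions and limitations

Coordinates are 0-based pixel centers, column = x, row = y (down); angles
are measured from +x toward +y and stored in degrees, [0°, 180°), float,
NaN for invalid — one convention everywhere, including files on disk
(TIFF + JSON sidecar, NIfTI with mm pixdim, NDJSON streamlines, JSON
transforms). `run_pipeline()` chains all stages deterministically under a
single seed and writes provenance (config hash, seed, package version,
stage timings) next to its artifacts; configurations are strict — unknown
keys are errors, named individually.

Known limitations: only in-plane orientation is measured (the through-plane
angle is invisible to this estimator, as it is to the instrument class);
the axis estimator is ambiguous beyond quarter-wave cumulative retardance;
the $\mu_s$ estimator is biased on shallow profiles; the forward model
omits speckle and multiple scattering; and the 2D tracker is not a
substitute for 3D tractography — it characterizes the orientation maps, it
does not reconstruct 3D connectivity.
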