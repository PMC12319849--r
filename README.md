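# psoctr

Polarization-sensitive optical coherence tomography (PSOCT) analysis of
white matter, with matched diffusion-MRI-style comparison — built for
researchers who study myelination and fiber architecture in ex vivo brain
tissue at micrometer resolution.

PSOCT detects two orthogonal polarization channels, giving complex depth
profiles `A₁,₂(z)·exp(iφ₁,₂(z))` per lateral position. Because the myelin
sheath is birefringent with its optic axis along the axons, four maps carry
the anatomy:

- reflectivity `R(z) ∝ A₁² + A₂²`
- retardance `δ(z) = arctan(A₁/A₂)` (degrees, [0°, 90°]) — rises with myelin
- optic-axis orientation `θ(z) = (φ₁ − φ₂)/2` (axial, [0°, 180°)) — the
  in-plane fiber direction
- scattering coefficient `µs(z) = I(z) / (2Δ Σⱼ₌z₊₁..d I(j))` (mm⁻¹), the
  depth-resolved attenuation estimate on the linear reflectivity signal

The package implements the whole analysis chain and, in place of physical
specimens, a synthetic birefringent fiber phantom with known ground truth:

| stage | functions |
|---|---|
| phantom + raw-data simulation | `phantom_spec()`, `region()`, `simulate_ascan()`, `simulate_volume()`, `simulate_tiled_acquisition()`, `simulate_dmri_maps()` |
| reconstruction | `fourier_reconstruct()`, `compute_reflectivity()`, `compute_retardance()`, `compute_axis()`, `compute_scattering_profile()`, `reconstruct_volume()` |
| en-face maps / mosaics | `enface_mean()`, `enface_orientation()`, `stitch()`, `stack_sections()` |
| 2D tractography | `build_mask_from_retardance()`, `seed_grid()`, `track()` |
| co-registration | `register_affine()`, `resample_map()`, `dice()`, `reorient_and_project()`, `make_masks()` |
| ROI statistics | `place_rois()`, `circ_mean_axial()`, `angular_difference()`, `pearson()`, `extract_roi_table()`, `wm_summary()`, `polar_histogram()` |
| pipeline | `read_config()`, `run_pipeline()`, `simulate_age_series()` |

## Worked example

Simulate a uniform myelinated phantom (µs = 4 mm⁻¹, Δn = 5×10⁻⁴, axis 32°,
5 µm axial pixels), reconstruct it, and collapse to en-face maps:

```r
library(psoctr)

spec <- phantom_spec(c(24, 24, 400), axial_pixel_um = 5, regions = list(
  region("box", mu_s = 4, birefringence = 5e-4, axis_deg = 32)))
vol  <- simulate_volume(spec, noise_sd = 0)
rec  <- reconstruct_volume(vol$ascan)
maps <- enface_stack(rec, depth_range = c(1, 200))

rec$retardance[12, 12, 20]   # 27.69  -- cumulative double-pass retardance
                             #           at 100 um: 2*(2*pi/1.3)*5e-4*100 rad
rec$theta[12, 12, 20]        # 32     -- the true axis, exactly
maps$mu_s_map[12, 12]        # 4.081  -- within ~2% of the true 4 mm^-1
                             #           (the tail-sum estimator's known
                             #            discretization bias)
maps$orientation_map[12, 12] # 32.5   -- histogram-peak estimate, quantized
                             #           to 5-degree bin centers
angular_difference(178, 1)   # 3      -- axial angles compared in polar space
```

`run_pipeline()` chains everything on a two-bundle demonstration phantom —
tiled acquisition with 20% overlap, per-tile reconstruction, mosaic
stitching, retardance-based white-matter masking, streamline tractography,
dMRI-style map generation, affine co-registration, and an ROI table with
PSOCT–dMRI correlations — deterministically for a fixed seed, writing maps,
streamlines, the transform, the ROI CSV and a provenance record when
`out_dir` is set.

`simulate_age_series()` runs five synthetic "ages" whose white-matter µs
rises about tenfold while birefringence rises and radial diffusivity falls,
then pools 120 white-matter ROIs across ages. With the default seed the
pooled correlations come out as `r(µs, ADC) = -0.98` and
`r(retardance, FA) = 0.93`: scattering anti-correlates with ADC and
retardance co-varies with FA, the expected signature of myelin maturation.

## Documentation

The methods vignette (`vignettes/psoct-white-matter-pipeline.Rmd`) explains
the forward model, each estimator and its failure modes, the design
decisions where the published processing left freedom, and what the
synthetic phantom does and does not emulate about real tissue.
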