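Package: psoctr
Title: Polarization-Sensitive OCT White-Matter Mapping and dMRI Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for polarization-sensitive
    optical coherence tomography (PSOCT) of white matter. Generates synthetic
    birefringent fiber phantoms with dual-channel complex depth profiles,
    reconstructs reflectivity, retardance, optic-axis orientation and the
    depth-resolved scattering coefficient, collapses volumes into en-face
    parameter maps with tile stitching and serial-section stacking, runs 2D
    orientation-field streamline tractography, performs affine cross-modal
    registration against diffusion-MRI-style parameter maps (ADC, FA,
    principal direction), and computes ROI-level circular statistics,
    Pearson correlations and polar-space angular differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
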