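Package: b0moco
Title: Motion-Corrected Brain MRI Reconstruction with Pose-Dependent B0 Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Retrospective, data-driven rigid-motion-corrected parallel-imaging
    (aligned-SENSE) reconstruction for volumetric Cartesian brain MRI that
    additionally models pose-dependent polarizing-field (B0) perturbations
    through voxelwise linear-coefficient maps in pitch and roll. Provides the
    encoding operators (shear-FFT rigid transforms, coil sensitivities,
    centered orthonormal Fourier transform, shot sampling masks), DISORDER
    random-checkered shot segmentation with an elliptical shutter, an
    alternating solver (conjugate-gradient image update, per-shot
    Levenberg-Marquardt motion update, gradient-descent B0-coefficient update
    with a phase-wrapping stabilizer) over a two-level multiresolution
    schedule, a field-map extraction and linear-coefficient fitting pipeline
    with 3D phase unwrapping, a synthetic k-space simulator with SNR-calibrated
    noise, and image-quality metrics (SNR, SSIM, mutual information, artifact
    power).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
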