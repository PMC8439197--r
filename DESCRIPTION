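Package: gmmaug
Title: Gaussian-Mixture Intensity Augmentation for Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Contrast augmentation for skull-stripped, bias-field-corrected
    T1-weighted brain MRI. Fits a per-image univariate Gaussian mixture over
    tissue intensities (CSF, GM, WM) by expectation-maximization, perturbs
    the component means and variances within calibrated uniform ranges, and
    reconstructs a contrast-altered image that preserves each voxel's
    Mahalanobis distance to its tissue component, blended by the original
    class posteriors. Includes a seeded synthetic brain-phantom generator
    (nested ellipsoidal tissue compartments, optional polynomial bias field
    and Rician noise), robust intensity normalizations, range calibration
    across image collections, NIfTI-1 input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
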