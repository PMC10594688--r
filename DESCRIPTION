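Package: airtrap
Title: Quantitative CT Assessment of Small Airway Disease from Paired
    Inspiratory/Expiratory Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies air trapping, the CT correlate of small
    airway disease, from paired inspiratory/expiratory chest CT volumes.
    Provides Hounsfield-unit-aware NIfTI and DICOM reading, threshold-based
    lung segmentation, 3-D affine registration of the expiratory scan into
    the inspiratory frame driven by mutual information, conventional
    densitometric metrics (mean lung attenuation, E/I and normal-density E/I
    ratios, attenuation-volume index, volume decrease ratio, low-attenuation
    area fractions), voxel-wise parametric response mapping (PRM) and air
    trapping index (ATI) maps, cohort-level statistics (correlations and
    their comparison, group tests, adjusted logistic regression, ROC
    cut-point selection, Bonferroni correction), and synthetic paired-CT
    phantoms and cohort simulators with closed-form oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    MASS,
    png,
    jsonlite,
    stats,
    grDevices,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
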