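Package: lunghetero
Title: Regional Heterogeneity of Emphysema from CT Densitometry and
    Oxygen-Enhanced MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chronic obstructive pulmonary disease (COPD) regional
    heterogeneity from two imaging modalities. For volumetric chest CT it
    performs tracheal-air Hounsfield-unit calibration, low attenuation volume
    (LAV) thresholding below -960 HU, isovolumetric cranial-caudal
    partitioning into 12 equal-volume parts with end exclusion, and reports
    whole-lung LAV% plus the across-partition standard deviation (SD-LAV).
    For oxygen-enhanced MRI time series it maps the per-pixel relative
    enhancement ratio (RER) between room-air baseline and 100% oxygen
    steady-state windows, and reports the lung-ROI mean (MRER) and the
    10-partition cranial-caudal standard deviation (SD-RER). A cohort layer
    provides normality-gated two-group comparison, gated Pearson/Spearman
    correlation, and bidirectional stepwise regression with standardized
    coefficients. Synthetic CT phantoms, oxygen wash-in series, and linked
    clinical covariates with known ground truth make every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort-gen.R'
    'cohort-stats.R'
    'ct-quant.R'
    'image-io.R'
    'lunghetero-package.R'
    'oemri-quant.R'
    'phantom-ct.R'
    'phantom-oemri.R'
    'pipeline.R'
    'utils.R'
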