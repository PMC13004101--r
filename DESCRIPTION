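Package: hrvofc
Title: Heart Rate Variability Band Power, Longitudinal Morphometry Change,
    and Partial Least Squares Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain linking heart-rate-variability (HRV) power during
    paced-breathing practice to longitudinal brain volume change and
    behavioral change. Provides inter-beat-interval cleaning, regime
    segmentation, 4-Hz interpolation, Welch spectral estimation with standard
    and custom low-frequency sub-bands, symmetrized percent change for
    three-timepoint volume panels, residualized partial correlations with
    robust variants (Spearman, Shepherd's pi) and Benjamini-Hochberg false
    discovery rate control, frequency-resolved correlation curves across
    breathing periods, and partial least squares correlation (PLSC) with
    permutation significance and bootstrap-ratio reliability. A synthetic-data
    generator with known planted structure supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
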