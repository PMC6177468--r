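Package: ramancyto
Title: Chemometric Discrimination of Cervical Cytology from Single-Cell Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for single-cell Raman spectra of
    exfoliated cervical epithelial cells. Provides a hierarchical synthetic
    spectrum generator (class, patient, cell type, band-level effects),
    non-negative least-squares glass-background removal, rubberband and
    iterative-polynomial baseline correction, vector normalization,
    from-scratch PCA-LDA and SIMPLS PLS-DA classifiers, random-subsets
    cross-validation with component selection by minimum cross-validation
    error, per-wavenumber two-sample t-test band detection, and study-level
    reporting of sensitivities and specificities for negative versus
    high-grade squamous intraepithelial lesion (HSIL) cytology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
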