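Package: biofilmq
Title: Quantification of Endoscopically Visible Mucosal Biofilms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify bacterial biofilms on the intestinal mucosa
    from confocal microscopy sections and multicenter endoscopy cohorts.
    Provides a synthetic-data generator for DAPI-like confocal sections with
    ground truth, a deterministic Laplacian-of-Gaussian spot detector, spatial
    metrics relative to a traced epithelial border (epithelium-adherent
    counts, field-maximum densities, a volumetric microscopic-biofilm
    criterion, surface-layer heights), cohort screening statistics (exclusion
    rules, prevalences, crude and center-adjusted odds ratios via grouped
    binomial regression, endoscopic-vs-microscopic concordance), and
    crystal-violet biofilm-formation assay scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
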