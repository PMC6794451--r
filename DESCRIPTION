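Package: seqstain
Title: Sequential Chromogenic IHC Registration, Quantification and Paired
    Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing sequential (multiplex) chromogenic
    immunohistochemistry of tumor biopsies: landmark-based least-squares
    co-registration of staining rounds (similarity or affine), optical-density
    conversion and stain deconvolution (hematoxylin with AEC or DAB
    chromogens), positive-cell detection and density quantification inside
    annotated tumor regions, cross-round cell matching for co-expression
    phenotyping, and the paired-cohort statistical layer (exact Wilcoxon
    signed-rank test, Spearman correlation, descriptives, treatment-group
    stratification). A deterministic synthetic slide and cohort generator
    provides ground-truthed inputs so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    polyclip,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
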