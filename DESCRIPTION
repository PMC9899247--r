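Package: metroute
Title: Metastasis Route Inference from Multi-Region Tumour Sequencing and Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the evolutionary route of distant metastases
    (lymphatic versus hematogenous seeding) from multi-region somatic variant
    data. Implements cross-region variant imputation ("fetch-back"), a
    read-count detection filter, cancer-cell-fraction (CCF) estimation with
    confidence-interval based clonal/subclonal calling, four-way selection
    classification of variants during metastatic seeding, neighbour-joining
    phylogenies on binary mutation matrices with mutation-resampling bootstrap
    and probabilistic route classification, density-based CCF clustering into
    subclones with adjustable-interval algebra and minimal-adjustment subclone
    tree reconstruction, and a sliding-window radiomics arm (statistical,
    grey-level co-occurrence and Gabor features) with a correlation-distance
    nearest-neighbour route predictor under leave-one-out cross-validation.
    A ground-truth clonal-evolution simulator generates every input the
    pipeline consumes, so the whole workflow is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
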