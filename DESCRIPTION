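Package: doseTrend
Title: Dose-Time Trend Screening for Chemotherapy-Induced Endothelial
    Gene Expression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Screens bulk expression profiles of drug-exposed endothelial
    cells for genes whose expression changes monotonically with dose across
    an ordered exposure ladder (control, IC50, IC90) at several time points.
    Implements the Cuzick rank test for linear trend, a time-summed Z
    composite score for ranking genes in acute exposure designs, two-sample
    t ranking for chronic low-dose designs, dual-direction top-k list
    construction with multi-setting overlap candidate selection, a gene-set
    enrichment analysis with a gene-label permutation null and FDR, qRT-PCR
    relative quantification, and longitudinal plasma-biomarker statistics
    (paired signed-rank, Mann-Whitney, Spearman correlation tracks).
    Ships synthetic-data generators that emulate the acute/chronic
    microarray designs and a multi-course plasma biomarker panel so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
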