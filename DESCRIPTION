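Package: symbioflux
Title: Constraint-Based Modeling of Symbiotic Nitrogen Fixation with
    Omics Concordance Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flux balance analysis (FBA), flux variability analysis (FVA)
    and in-silico gene deletion for gene-protein-reaction (GPR) annotated
    metabolic reconstructions of nitrogen-fixing rhizobial bacteroids,
    driven by a metabolite-production objective that mimics symbiotic
    nitrogen fixation.  Includes the consistency-coefficient framework
    that scores the agreement between model-predicted active gene and
    enzyme sets and transcriptome- or proteome-derived sets
    (hypergeometric enrichment, per-pathway three-way breakdowns), the
    z-score selection procedure for replicated microarray log-ratios, and
    a synthetic-data module that generates toy bacteroid networks and
    omics data with known ground truth so that every pipeline stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
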