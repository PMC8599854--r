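Package: tumorith
Title: Immunogenomic Intratumor Heterogeneity Analysis for Multi-Region Tumor Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-region tumor whole-exome and T-cell
    receptor (TCR) sequencing studies of intratumor heterogeneity (ITH).
    Implements somatic variant quality control with an FFPE log-odds rescue
    rule, trunk/branch/private mutation classification, Wagner-parsimony
    phylogenies rooted at germline, cancer-cell-fraction estimation and
    clonal architecture clustering, gene-level copy-number aberration and
    loss-of-heterozygosity classification, HLA loss-of-heterozygosity and
    neoantigen immune-escape summaries, TCR-beta repertoire diversity and
    overlap metrics, trunk-versus-nontrunk mutational-signature refitting,
    and cohort-level survival statistics. A synthetic-cohort generator with
    known ground truth makes every stage testable without controlled-access
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    mclust,
    pracma,
    survival,
    ape,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
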