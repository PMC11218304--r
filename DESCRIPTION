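Package: rarecollapse
Title: Rare-Variant Collapsing Burden Analysis with Exact Stratified
    Cochran-Mantel-Haenszel Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A case/control rare-variant collapsing (burden) analysis
    toolkit: variant- and sample-level quality control of annotated VCF
    cohorts, case/control coverage harmonization, qualifying-variant
    models with per-population gnomAD and internal allele-frequency
    gates and an intolerant-domain (subRVIS percentile) restriction,
    gene- and domain-unit dominant collapsing, an exact two-sided
    Cochran-Mantel-Haenszel test meta-analysed across ancestry clusters
    with Mantel-Haenszel pooled odds ratios, permutation-based empirical
    null distributions with QQ bands and genomic inflation, and tiered
    gene-set burden enrichment. Includes a deterministic cohort
    simulator with planted signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
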