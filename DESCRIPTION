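Package: faersignal
Title: Disproportionality Analysis and Signal Clustering for Spontaneous
    Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection from FAERS-style
    spontaneous adverse-event report databases. Reads "$"-delimited quarterly
    DEMO/DRUG/REAC/INDI tables, deduplicates case versions, restricts drugs to
    primary and secondary suspects, and normalizes verbatim drug names to a
    configurable target vocabulary (shipped rules cover eleven mu-opioid
    receptor agonists). Computes per drug-event pair reporting odds ratios with
    the Haldane-Anscombe 1/2 correction, log-scale Wald confidence intervals,
    and two-sided Fisher exact screening; assembles the drug-by-event lnROR
    matrix with report-count and mean-lnROR filters; and classifies both axes
    by Ward agglomerative hierarchical clustering with heatmap-ready exports.
    A synthetic report generator with planted reporting-rate multipliers and a
    closed-form expected lnROR oracle supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
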