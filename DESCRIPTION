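Package: hltme
Title: Tumor-Microenvironment Characterization of Classic Hodgkin Lymphoma by HLA Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterizing the tumor microenvironment (TME)
    of classic Hodgkin lymphoma stratified by HLA class I / class II expression on
    Hodgkin-Reed-Sternberg cells (HRSCs). Implements differential bulk gene
    expression with logistic generalized linear models and an optional EBV
    confounder, Benjamini-Hochberg adjustment and volcano classification;
    spatial zoning of multiplexed-immunofluorescence cell maps by distance to
    the nearest HRSC with phenotype composition per zone and paired zone
    comparisons; Simpson's clonality of TCR-beta repertoires; and
    contingency-table association statistics (two-sided Fisher exact test by the
    point-probability rule, Pearson chi-square). A synthetic cohort generator
    (marked point processes for cell maps, negative-binomial counts, Dirichlet
    clone frequencies) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
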