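Package: lsexpand
Title: Lineage-Specific Gene Family Expansions: Detection, Expression
    Divergence and Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the history of lineage-specific gene
    family expansions from gene trees, illustrated on G-protein-coupled
    receptor (GPCR) repertoires. Detects maximal lineage-restricted clades in
    gene trees with branch-support filtering, extracts each expanded group
    with its closest well-supported outgroup, and summarises patristic
    divergence. Profiles tissue specificity with the Tau index, expression
    proportions, and non-parametric group comparisons (Kruskal-Wallis, Dunn's
    post hoc test with Holm adjustment). Tests for positive selection with
    Goldman-Yang codon models: protein-to-CDS back-translation, codon-aware
    alignment cleaning, M0, two-ratio branch and M1a/M2a site model fits by
    maximum likelihood with likelihood-ratio tests and naive empirical Bayes
    site posteriors. Summarises genomic co-localization (tandem duplication
    clusters) from scaffold coordinates. A synthetic-data module generates
    gene trees with planted expansions, tissue-structured expression,
    codon alignments evolved under known per-branch dN/dS, and scaffold
    layouts with planted tandem arrays, so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
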