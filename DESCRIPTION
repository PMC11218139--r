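Package: mgtools
Title: Statistical Toolkit for Shotgun Metagenomics and Multi-Omics
    Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable statistical engine for shotgun-metagenomics count
    tables and companion omics tables. Provides alpha diversity (Shannon,
    Gini-Simpson, Pielou), phylogenetic community-assembly indices (MPD,
    MNTD and their standardized effect sizes NRI/NTI under a taxon-label
    null model), unconstrained ordination (PCA, principal coordinates on
    Bray-Curtis distances), distance-based hypothesis tests (PERMANOVA,
    fuzzy set ordination), nonparametric differential abundance
    (Kruskal-Wallis and Friedman with Dunn post hoc and false-discovery
    control), KEGG ortholog pathway over-representation, and two-block
    joint decomposition of paired omics matrices (DISCO-SCA, JIVE, O2PLS).
    Includes readers for CSV/TSV feature tables, sample metadata, mapping
    tables and newick trees, sample-identifier harmonization across
    datasets, and seeded synthetic-data generators with planted structure
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    tools,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
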