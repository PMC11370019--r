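Package: vgccraft
Title: Headless Variant Cohort Indexing, Querying and Genotype-Phenotype Association for VCF Files
Version: 0.1.0
Authors@R: person("VGCcraft", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A headless engine for browsing case-control variant cohorts stored
    in Variant Call Format (VCF) text files. Builds a human-readable sidecar
    index (per-chromosome line and position spans with PASS and pathogenic
    counts) for fast repeated access, retrieves variants by gene symbol,
    genomic range or batch file under ALL/PASS/Pathogenic filters, joins
    variants against a local ClinVar-style pathogenicity table, constructs
    gnomAD link-out URLs and MSigDB-style gene-set memberships, and tests
    genotype-phenotype association per variant with Fisher's exact test on
    group-by-genotype contingency tables, computed both by exact enumeration
    and by Monte Carlo simulation from the fixed-margin hypergeometric null
    (default 2000 simulations). Also provides the data models behind histogram
    (with recursive zoom), bipartite variant-sample node-graph and genotype
    heat-map views, spreadsheet-style export, a synthetic case-control cohort
    simulator for fully self-contained testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
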