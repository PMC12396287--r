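Package: omicsbridge
Title: Bridge-Protein Discovery on PPI Networks, Interferon Scores and
    Cohort Genotype-Phenotype Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for connecting a target protein to differentially
    abundant proteins (DAPs) on a STRING-style protein-protein
    interaction network via random-walk node embeddings (DeepWalk-style
    walks factorized by PPMI plus truncated SVD, with optional
    annotation-membership blocks), including discovery and ranking of
    intermediary (bridge) proteins, central-protein selection and
    hypergeometric term enrichment with Benjamini-Hochberg FDR.  Also
    implements DAP threshold filtering and replicate intersection,
    2^-ddCt relative quantification with a six-gene type I interferon
    signature score compared by exact Mann-Whitney U, and cohort
    phenotype-frequency aggregation with variant hotspot-cluster
    assignment and exact two-sided Fisher tests.  Synthetic-data
    generators (planted-bridge graphs, qPCR Ct tables, cohorts, paired
    DAP tables) provide ground-truthed inputs for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
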