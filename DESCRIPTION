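Package: ppirescore
Title: Post-Docking SASA Descriptors, Consensus Rescoring and Machine
    Learning for Virtual Screening on Protein-Protein Interfaces
Version: 0.1.0
Authors@R:
    person("ppirescore", "developers", email = "ppirescore@example.org",
           role = c("aut", "cre"))
Description: Tools to post-process protein-ligand docking poses for
    virtual screening against protein-protein interaction (PPI) targets.
    Computes Shrake-Rupley solvent-accessible surface area (SASA) of a
    docked complex in bound and unbound states, partitions it over seven
    pharmacophoric atom categories, and derives an ordered vector of 80
    receptor, ligand and receptor-ligand SASA descriptors per pose.
    Also provides min-max score normalization with rank-by-rank consensus
    aggregation of heterogeneous scoring functions, early-recognition
    screening metrics (ROC AUC, enrichment factors, BEDROC), eight binary
    classifier families trained on descriptor tables with stratified
    splitting and cross-validation, and synthetic fixture generators for
    fully self-contained testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
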