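Package: panscreen
Title: Phage-Display Panning Screens: NGS Enrichment, Clustering and
    Aggregation-Kinetics Analysis
Version: 0.1.0
Authors@R:
    person("Panscreen", "Developers", email = "panscreen@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for phage-display selections of small
    scaffold-protein libraries against amyloid-beta species. Covers library
    design and diversity accounting, FASTQ quality control and in-silico
    translation of variable-region reads, enrichment ranking and
    cross-selection overlap analysis, ungapped peptide similarity scoring
    with cutoff clustering and sequence logos, two-moment amyloid
    aggregation kinetics with selective-inhibition model selection, and
    binding-readout arithmetic (FRET transfer efficiency, hydrodynamic
    radius to molecular weight scaling). Includes a seeded synthetic
    panning simulator so the full pipeline is testable without external
    sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
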