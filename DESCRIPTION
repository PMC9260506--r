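Package: mimoseq
Title: Paired-Chain TCR Repertoire Analysis and Mimotope Library Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering public T cell receptor (TCR) responses and
    engineering cross-reactive peptide mimotopes. Implements plate-barcoded
    paired single-cell TCR amplicon processing (demultiplexing, read collapse,
    V/J annotation, CDR3 extraction, clonotype calling and clonality
    summaries), CDR3 motif and convergent-recombination analytics,
    tetramer-fraction clonotype enrichment, NNK saturation-mutagenesis
    library design with selection-round deep-sequencing analysis
    (position-preference matrices, enrichment trajectories, candidate
    ranking), and small quantitative assay fits (steady-state one-site
    binding, thermal-melt midpoints, ROUT outlier flagging, in vivo
    specific-killing readouts). Seeded synthetic-data generators with
    planted ground truth emulate every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    methods,
    minpack.lm,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
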