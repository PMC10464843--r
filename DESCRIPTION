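Package: tcrpmhc
Title: Template-Anchored Modeling and Interface Analysis of TCR CDR3 Mutation Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for template-anchored structural analysis of T-cell receptor
    (TCR) recognition of peptide-MHC complexes. Clusters CDR3 specificity
    records around template cores taken from solved structures, enumerates
    stepwise single-substitution mutation pathways, builds child models through
    a pluggable mutation backend with a deterministic side-chain surrogate,
    detects and classifies CDR3-peptide contacts, computes interface energies
    under restricted term presets with per-residue decomposition, relates
    energy changes to substitution-matrix indices and amino-acid descriptor
    scales, and trains recursive-feature-elimination random-forest models of
    per-residue contact energy. A synthetic-data module generates planted
    repertoires, toy complexes and descriptor-energy tables so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    yaml,
    jsonlite,
    Biostrings,
    randomForest,
    caret,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
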