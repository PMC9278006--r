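Package: capriqa
Title: CAPRI-Criteria Quality Assessment of Protein Complex Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing predicted protein-protein complex models
    against experimentally determined reference structures using the CAPRI
    criteria (fraction of native contacts, interface RMSD, ligand RMSD, and
    the high/medium/acceptable/incorrect accuracy classes), for computing
    interface-restricted confidence metrics (interface pLDDT and interface
    PAE) from AlphaFold-style per-residue and pairwise confidence outputs,
    for assembling unpaired and paired complex multiple sequence alignments
    with gap padding and chain-break index shifts and measuring their depth
    (Neff by greedy identity clustering), and for quantifying how well any
    per-model score discriminates accuracy classes (ROC AUC with stratified
    bootstrap confidence intervals, optimal sensitivity plus specificity
    cutpoints, rank-sum tests, correlations).  A synthetic-benchmark
    generator builds toy two-chain complexes with rigid-body decoy series of
    analytically known ligand RMSD and fabricated confidence maps, so the
    full assessment pipeline can be exercised end to end without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
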