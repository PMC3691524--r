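Package: phylocofold
Title: RNA Consensus Secondary Structure Prediction with Phylogenetic
    Covariation Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts a consensus secondary structure for a multiple RNA
    sequence alignment by minimum-free-energy dynamic programming, with a
    covariance score that rewards compensatory (covarying) base-pair
    substitutions between alignment columns.  The covariance score can be
    scaled by the number of covarying mutations counted on a rooted binary
    phylogenetic tree of the aligned sequences via a gap-aware forward
    Fitch parsimony pass, so that column pairs whose compensatory changes
    recur independently across the phylogeny receive a larger pairing
    bonus.  Includes Stockholm/CLUSTAL/FASTA alignment I/O, Newick tree
    handling, Jukes-Cantor distances with UPGMA tree construction, a
    pluggable loop-energy model, base-pair-level accuracy evaluation
    (Matthews correlation coefficient with contradictory-versus-compatible
    false-positive handling), and a synthetic alignment generator for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
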