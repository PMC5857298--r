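Package: ldspace
Title: Proteome Fingerprints and Alignment-Free Phylogenies in
    Length-Disorder Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies whole proteomes by the joint distribution of protein
    length and intrinsic disorder content. Each proteome is reduced to a
    normalized M x N density grid (a "fingerprint") over the plane spanned by
    ln(protein length) and per-protein disorder content; pairwise Euclidean
    distances between fingerprints feed a neighbor-joining tree, giving an
    alignment-free phylogeny. Includes FASTA ingestion with longest-isoform
    selection, per-residue disorder score handling with a propensity-based
    proxy scorer, tabular proteome summaries, length-disorder correlation
    statistics, a synthetic-proteome generator for self-contained testing, and
    contour-map rendering of fingerprints and differential fingerprints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
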