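Package: mipscan
Title: Ab Initio MicroProtein Discovery, B-Box Motif Analytics and
    Gene-Set Overlap Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens a proteome for microProtein candidates: small,
    single-domain proteins carrying a protein-protein-interaction (Pfam)
    domain that are related to larger, multi-domain proteins which they can
    sequester into non-functional complexes. Resolves raw domain hits into
    non-overlapping per-protein domain architectures, pairs each candidate
    with its putative larger targets, and groups candidates into families.
    Ships a residue-class/spacer consensus grammar with scanners for
    zinc-finger B-Box classification (CO/COL-type versus miP1-type) and for
    C-terminal TOPLESS-recruitment motifs (PF(V/L)FL, EAR/LxLxL), protein
    variant builders (B-Box C/H-to-A knockout, C-terminal truncation),
    global pairwise alignment with percent-identity conventions, exact
    hypergeometric gene-set overlap tests, and seeded synthetic generators
    (planted candidate/target proteomes with criterion-specific decoys,
    consensus-conforming B-Box sequences, gene-ID sets with controlled
    overlap) that serve as a download-free test bed. A command-line entry
    point exposes scan, motif, identity, overlap and simulate subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
biocViews: SequenceMatching, Alignment, MotifDiscovery, Proteomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
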