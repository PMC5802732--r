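Package: atdkit
Title: Structural and Functional Signatures of Animalia-Specific tRNA Deacylase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis that distinguishes the
    Animalia-specific tRNA deacylase (ATD) from its paralog, D-aminoacyl-tRNA
    deacylase (DTD). Provides geometric classification of the cross-subunit
    Gly-Pro active-site motif (cis versus trans peptide bond, carbonyl
    orientation, B-factor rigidity, side-chain contacts), iterative Kabsch
    superposition of protein structures, signature-motif classification of
    deacylase sequences, scanning of tRNA acceptor stems for the G4:U69
    wobble pair with per-isotype enrichment and presence/absence
    co-occurrence testing, and first-order deacylation kinetics with
    substrate-discrimination and EF-Tu protection factors. A synthetic-data
    module generates structures, sequences, tRNA gene sets, and decay time
    courses with known ground truth so that every stage can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
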