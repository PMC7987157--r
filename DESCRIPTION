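Package: srpAncestry
Title: Ancestral Sequence Reconstruction and Amino-Acid Chronology
    Analysis for the SRP/Sec Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Marginal ancestral sequence reconstruction for protein
    alignments under the WAG substitution model, with maximum-likelihood
    inference of gaps as a binary presence/absence character,
    cluster-based dataset reduction with replicate reconstructions and
    simple-majority consensus, a WAG-simulation null for amino-acid
    genetic-code chronology analysis (late-amino-acid depletion tests),
    Gblocks-style conserved-block trimming, and sequence-level
    physicochemical calculators (isoelectric point, hydropathy,
    membrane-targeting-sequence extraction). Designed around the
    signal-recognition-particle (Ffh/FtsY) and SecY protein families,
    whose basal duplication predates the last universal common ancestor,
    but applicable to any gapped amino-acid alignment with a guide tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    seqinr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
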