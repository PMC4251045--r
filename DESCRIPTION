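Package: xlms
Title: Cross-Linked Peptide Search for Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification of chemically cross-linked peptide pairs from
    tandem mass spectrometry peak lists. Builds pairwise candidate databases
    from protein sequences by in-silico digestion with cross-linkable site
    filters, matches precursors within a ppm tolerance, scores candidates
    with a b-ion to complementary-y-ion fragment filter, localizes the
    cross-linked residues, and validates results by reversed-sequence decoy
    false discovery rates and a relaxed-specificity ROC analysis. Supports
    amine-reactive (DSS) and photo-activatable semi-specific (SDA)
    cross-linkers, 15N metabolic labeling, MGF and NIST MSP input, and
    includes a seeded simulator of CID spectra of cross-linked tryptic
    peptide pairs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
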