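Package: mfsa
Title: Modular Fragmentation-Based Structure Assembly for Targeted
    Annotation of Complex Natural Products from LC-MS/MS Data
Version: 0.1.0
Authors@R:
    person("MFSA", "Developers", email = "mfsa@example.org", role = c("aut", "cre"))
Description: Targeted structural annotation of complex natural products
    (proof-of-concept class: daphnane-type diterpenoids) from LC-MS/MS
    feature exports. Builds a combinatorial pseudo-compound library from
    labeled structure fragments with predicted diagnostic product-ion
    formulas under a per-submodule element mass-shift model, recognizes
    class members by formula matching at ppm tolerance inside a
    max-min-normalized m/z window, determines precursor formulas and
    adducts de novo by exhaustive CHON enumeration with an RDBE filter,
    labels carbon-count-constrained neutral-loss ion pairs and diagnostic
    feature ions with intensity-based scores, computes range-limited
    cosine similarity, and assembles and ranks candidate structures by a
    priority score. Includes a synthetic MZmine-style fixture generator
    and a library-degradation sensitivity harness, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (used for SMILES fragment merging and canonicalization).
Config/testthat/edition: 3
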