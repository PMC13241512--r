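Package: SpectraMol
Title: Cross-Modal Spectrum-Molecule Alignment and Structure Elucidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Retrieve-then-refine computer-assisted structure elucidation at
    desk scale. Encodes 1H/13C NMR, IR and HSQC spectra and SMILES strings
    into a shared embedding space with contrastively trained (symmetric
    InfoNCE) neural encoders, retrieves candidate molecules from a
    formula-filtered index by multimodal cosine similarity, refines the
    candidate population with a graph genetic algorithm scored by embedding
    similarity minus a molecular-formula penalty, and calibrates the
    resulting scores against empirical accuracy. Ships a synthetic-chemistry
    module that generates molecule corpora and rule-based toy spectra so the
    whole pipeline is trainable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
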