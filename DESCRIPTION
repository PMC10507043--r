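Package: calvinreg
Title: Metabolite-Level Regulation of the Bacterial Calvin Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying metabolite-level regulation of the bacterial
    Calvin cycle. Implements limited-proteolysis (LiP-SMap) metabolite-protein
    interaction calling from replicate peptide intensities with
    Benjamini-Hochberg control, cross-species ortholog binarization with PCA
    and Ward-clustered category heatmaps, Malachite-Green/Hill-equation enzyme
    kinetics and nanoDSF thermal-shift analytics, and an ensemble kinetic
    model of Synechocystis central carbon metabolism with thermodynamically
    constrained parameter sampling, Jacobian stability classification, and
    metabolic control analysis comparing a base model variant against a
    variant with GAP activation and NADPH inhibition of F/SBPase. Synthetic
    data generators with recorded ground truth exercise every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
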