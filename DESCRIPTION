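Package: aexms
Title: Proteoform Assignment and Quantification for Anion-Exchange
    Chromatography-Mass Spectrometry of Intact Glycoproteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing proteoforms of heavily sialylated
    glycoproteins such as alpha-1-acid glycoprotein (AGP) from intact-protein
    anion-exchange chromatography coupled to mass spectrometry (AEX-MS).
    Provides average-mass arithmetic for protein-level glycan compositions,
    enumeration of candidate glycoforms per genetic variant under
    composition constraints, matching of observed deconvoluted masses with
    a retention-derived sialic-acid-count constraint that resolves
    near-isobaric compositions, charge-ladder deconvolution and
    extracted-ion-chromatogram quantification of raw scan data, per-variant
    relative quantification with sialylation, fucosylation and branching
    summaries, condition comparison, and a synthetic AEX-MS data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
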