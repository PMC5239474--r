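Package: phosforest
Title: Phosphorylation-Site Prediction with an Ensemble of Pseudo-Component Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts phosphorylation sites (phosphoserine, phosphothreonine,
    phosphotyrosine) in protein sequences. Thirteen-residue peptide windows
    centered on candidate S/T/Y residues are encoded under four
    pseudo-component feature views (per-residue intrinsic-disorder scores,
    BLOSUM62 k-nearest-neighbor label fractions, amino-acid occurrence
    frequencies, and position-weighted attribute-group composition), one
    random forest is trained per view, and the four votes are fused by
    majority into an ensemble call. Includes benchmark-dataset construction
    from annotated FASTA proteomes, imbalance-aware balanced-subset
    evaluation with stratified five-fold cross-validation, sensitivity /
    specificity / accuracy / Matthews-correlation metrics with ROC/AUC
    reporting, a synthetic annotated-proteome generator with controllable
    signal strength, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
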