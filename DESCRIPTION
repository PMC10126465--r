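Package: sporekinetics
Title: Spore Germination Kinetics, Thermal Inactivation and Duf421 Homolog
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of bacterial spore phenotyping assays:
    extraction of single-spore phase-contrast intensity traces from
    time-lapse stacks and changepoint fitting of the three-phase
    germination model (Tlag, Trelease, Tlys), population germination
    metrics from Tb-DPA fluorescence curves, relative CaDPA quantitation,
    viable-titer reconstruction and decimal-reduction-time (D-value)
    estimation from serial-dilution spotting assays, and length- and
    alignment-based classification of Duf421-family proteins into
    YetF-like and 2Duf-like groups. A synthetic-data generator produces
    ground-truth-bearing image stacks, plate-reader curves, colony-count
    tables and labeled protein sets so that every stage of the pipeline
    can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
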