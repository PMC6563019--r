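Package: glycopipe
Title: Untargeted LC-MS Glycopeptide Profiling with QC Normalization and
    OPLS-DA Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for untargeted serum glycopeptide
    profiling by liquid chromatography mass spectrometry: extracted-ion
    chromatogram construction, Savitzky-Golay smoothing with
    derivative-based peak bounding and trapezoidal area integration,
    internal-standard retention-time and m/z drift correction, tolerance
    based cross-run alignment, pooled-QC ratio normalization with inter-
    and intra-assay coefficient-of-variation reporting, a four-stage
    feature filter cascade (blank comparison, CV, signal-to-noise,
    isotope/adduct/in-source-fragment deduplication), and two-class
    discrimination by PCA and orthogonal projections to latent structures
    discriminant analysis (OPLS-DA) with R2X/R2Y/Q2 cross-validation,
    volcano statistics and heat-map ratio matrices. A synthetic-cohort
    generator with full ground truth makes every stage testable without
    raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    mzR
Config/testthat/edition: 3
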