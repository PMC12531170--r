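Package: scfamsi
Title: Derivatization Mass Modelling, Ion Imaging and Bacterial
    Proteotyping for Short-Chain Fatty Acid MALDI-MSI
Version: 0.1.0
Authors@R:
    person("scfamsi", "developers", email = "scfamsi@example.org",
           role = c("aut", "cre"))
Description: Tools for on-tissue chemical derivatization workflows in
    MALDI mass spectrometry imaging of carboxylic acids, built around the
    quaternary-amine tag TMPA (N,N,N-trimethyl-2-(piperazin-1-yl)ethan-1-amine).
    Computes theoretical m/z for derivatized acids and matrix interference
    ions from elemental formulas with pinned isotope masses and atomic
    weights; reads and writes imzML and a plain-text pixel-grid format;
    extracts ion images at a theoretical m/z within a tolerance window,
    normalizes, and compares signal across anatomical region masks.
    Also identifies cultured gut bacteria by matching linear-TOF peak
    lists against predicted average masses of ribosomal proteins, and
    estimates colony-forming units from Miles-Misra dilution series.
    A seeded synthetic-data module generates tissue phantoms and protein
    spectra with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
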