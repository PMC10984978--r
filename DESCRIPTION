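Package: nanofrac
Title: Bioactivity-Correlated Feature Detection and Molecular Networking
    for At-Line Nanofractionation LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs bioactivity chromatograms from nanofractionated
    384-well plate assays, aligns them with parallel LC-MS/MS data using a
    calibrant-derived tubing delay, detects chromatographic features with an
    MZmine-style centroiding, chromatogram-building and local-minimum
    deconvolution chain, builds modified-cosine molecular networks over
    paired MS2 spectra, and correlates bioactive fractions with mass
    features including in-source fragment and adduct annotation. Ships a
    ground-truthed synthetic data generator (Gaussian elution, isotope
    envelopes, data-dependent MS2, plate readouts with activity dips) so the
    whole pipeline runs and is testable offline, plus readers and writers
    for mzML, mzXML, MGF, GraphML and FBMN-style quantification tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
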