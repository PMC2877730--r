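Package: akhquant
Title: Quantitative Direct MALDI-TOF Profiling of Adipokinetic Hormone in
    Single Corpora Cardiaca
Version: 0.1.0
Authors@R:
    person("CC", "Profiling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for absolute quantification of the insect neuropeptide
    adipokinetic hormone (AKH) and its processing intermediate AKHGK in
    direct MALDI-TOF mass profiles of single corpora cardiaca, using a
    stable-isotope-labelled internal standard (AKH*). Includes peptide
    monoisotopic-mass and adduct calculators, a prohormone-convertase
    processing model for the AKH precursor, a synthetic-spectrum generator
    with known ground truth, spectrum processing (top-hat baseline
    correction, peak detection, de-isotoping, adduct assignment),
    internal-standard ratio quantification with calibration diagnostics,
    and nonparametric cohort comparison (Mann-Whitney U).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
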