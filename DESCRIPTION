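Package: aznano
Title: Nanoscale Organization Analysis of Active Zone Proteins from
    Single-Molecule Localizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed DNA-PAINT localization data of
    synaptic proteins: localization table input/output and rendering, quality
    filtering, temporal linking of blinking events, redundant cross-correlation
    drift correction, polynomial chromatic registration, scaffold-based synapse
    selection with alpha-shape boundaries, DBSCAN nanocluster detection,
    pair autocorrelation, randomization-normalized cross-enrichment with
    outlier smoothing, a nanocluster separation index, a synthetic-data
    generator with planted ground truth, and STED side-view line-profile
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
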