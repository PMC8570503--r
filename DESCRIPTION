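Package: airwaymorph
Title: Upper-Airway CT Morphometry and Test-Retest Variation Analysis
Version: 0.1.0
Authors@R:
    person("Airway", "Morph Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Landmark-driven segmentation and morphometric analysis of the
    pharyngeal airway in computed-tomography volumes. Extracts the airway
    lumen between the posterior nasal spine and the base of the epiglottis,
    removes disconnected air ("islands") and re-entrant pockets ("dead
    space"), partitions the lumen into the velopharynx, oropharynx,
    tongue-base and epiglottis slabs, and computes volume, length, open and
    closed surface area, minimum cross-sectional area with its lateral and
    anteroposterior extents, mean cross-sectional area, uniformity and
    sphericity per region. Includes a synthetic paired-scan CT phantom
    generator with analytically known ground truth, and the between-scan
    variation statistics used in test-retest airway studies: relative
    differences, intraclass correlation coefficients, Bland-Altman limits of
    agreement and the smallest detectable difference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
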