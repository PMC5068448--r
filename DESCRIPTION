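Package: gelquant
Title: Quantitative Scoring of Genomic DNA Quality from Agarose Gel Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automates the "greater than X kb" agarose-gel densitometry
    standard for genomic DNA quality. Loads grayscale gel images, inverts,
    levels and background-subtracts them, extracts per-lane intensity
    profiles, locates DNA-ladder band apexes, interpolates a DNA-threshold
    line between flanking ladder lanes, and reports the percent of each
    sample's DNA signal at or above the chosen ladder band size, using the
    GGBN Gel Image Vocabulary terms DNAThreshold and percentAboveThreshold.
    Includes a Gage repeatability-and-reproducibility ANOVA for scoring
    consistency studies and a forward simulator of gel images with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
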