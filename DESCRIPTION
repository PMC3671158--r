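Package: xmapqc
Title: Analysis and Quality Control of Multiplexed Bead-Array Immunoassay Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Parses Bio-Plex-Manager-style Excel run workbooks from Luminex
    xMAP multiplexed bead-array immunoassays, normalizes fluorescence
    intensities (blank-bead and background-well subtraction, floor-and-shift
    conversion, optional log transform), fits weighted four- and
    five-parameter logistic titration curves, derives EC50, trapezoidal AUC
    and HighMFI, interpolates unknown concentrations from standard curves,
    applies replicate percent-CV flagging and exclusion with recomputation,
    and tracks curve metrics across runs with guide sets and Levey-Jennings
    bands. A synthetic-data generator emulates instrument workbooks with
    known ground truth so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    readxl,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml,
    zip
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
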