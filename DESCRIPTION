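Package: skinlipidr
Title: Quantitative Shotgun Lipidomics of Tape-Stripped Skin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative, high-throughput shotgun lipidomics toolkit for
    tape-stripped stratum corneum samples. Implements a lipid-species naming
    grammar covering twelve ceramide subclasses plus cholesterol, cholesteryl
    esters, di- and triacylglycerols; combinatorial candidate enumeration with
    precursor inclusion lists and per-class MSMS fragment rules; isotope
    envelope computation with type I (inter-species isotopologue overlap) and
    type II (non-monoisotopic fraction) intensity correction; ppm-gated
    precursor and fragment matching with a strict quality-filter cascade
    (lock-mass dependent ppm gates, signal-to-noise, blank fold-change,
    replicate occurrence, minimum amount); absolute quantification against
    spiked deuterated internal standards; an in-silico spectrum generator for
    validation; and the downstream survey statistics used in skin-lipidome
    studies (replicate CVs, dynamic-range fits, depth profiles, PCA,
    correlation-based site clustering, repeated cross-validated random-forest
    sex classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    caret,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse,
    withr
Config/testthat/edition: 3
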