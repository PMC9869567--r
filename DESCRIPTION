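Package: bubblecov
Title: Coverage Statistics for Ligand-Induced DNA Melting Bubbles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline relating dinuclear-complex adsorption to the
    formation of melting bubbles in double-stranded DNA. Implements random
    sequential adsorption of dimeric ligands on two single-strand lattices to
    jamming, extraction of antiphasic ("zigzag") packing segments, maximal
    AT-run analysis of genome sequences, the combination of both conditions
    into dissociation-propensity coverage curves, and the conversions and
    summary statistics (nm per base pair, bubble coverage, feature-distance
    histograms) used to compare the curves against atomic force microscopy
    measurements. Includes seeded synthetic-data generators for genomes,
    bubble-length samples and distance samples so the full analysis runs
    without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
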