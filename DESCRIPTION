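Package: mutsigexp
Title: Detection and Characterisation of Experimentally Generated Mutational Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for mutational-signature experiments in
    single-cell-derived subclones of cellular model systems. Classifies somatic
    mutations into signature channels (96 single-base substitution channels,
    78 strand-agnostic doublet channels, indel and rearrangement channels),
    builds channel-by-sample catalogs, performs lineage and clonality quality
    control from shared variants and variant allele fractions, tests mutation
    burdens of treated subclones against a control-derived null, quantifies
    profile separation with a signal-to-noise ratio, and extracts
    experiment-associated signatures by bootstrap subtraction of the background
    (control) signature with per-channel confidence intervals. Includes a
    synthetic lineage and mutation generator so the whole pipeline can be
    exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    methods,
    vcfR,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
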