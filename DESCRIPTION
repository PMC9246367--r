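Package: ratemixr
Title: Rate Mixing, Site-Pattern Asymmetry and Ancestry Entropy Across Hybrid Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how cross-species gene flow mixes divergent
    genomic substitution rates across a hybrid zone. Implements windowed
    population-genetic statistics (Hudson's FST, DXY, nucleotide diversity)
    with block-jackknife standard errors; spectral-entropy metrics for
    unphased diploid local-ancestry signals (within- and between-individual
    entropy); three- and four-taxon site-pattern asymmetry statistics (D3,
    the ABBA-BABA D4) together with closed-form recurrent-mutation theory for
    their expected biases; the observed substitution-rate ratio and its
    relationship to relative divergence (FST) under an equilibrium
    isolation-with-migration coalescent model; and seeded coalescent
    simulators (two-deme pair, multi-window landscape, stepping-stone,
    site-pattern and block-ancestry generators) so every stage of the
    analysis can be validated against theory on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
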