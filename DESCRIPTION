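Package: migmod
Title: Selection on Modifiers of Genetic Architecture Under Migration Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic multilocus machinery for quantifying selection on
    modifiers of genetic architecture in a two-deme population at
    migration-selection balance. Builds exact gamete-production tables for a
    linear linkage map, computes diploid fitness with logistic dominance and
    epistasis, iterates the two-deme life-cycle recursion to the polymorphic
    equilibrium, and measures the strength of selection on rare modifier
    alleles (of recombination, dominance, epistasis, dispersal, or the total
    cost of maladaptation) as the dominant eigenvalue of the invasion matrix.
    Includes preset parameter sweeps, broom-style tidiers, and ggplot2 plots.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
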