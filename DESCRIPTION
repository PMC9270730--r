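Package: nbloop
Title: Chromatin Loop Detection in Hi-C Contact Matrices via Continuous
    Negative Binomial Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects chromatin loops in balanced Hi-C contact matrices.
    Per genomic distance, observed/expected contact values are fitted to a
    continuous negative binomial distribution (gamma-function continuation
    of the discrete probability mass function) and enriched pixels are
    preselected by right-tail p-values, an observed/expected threshold and
    a raw interaction-count filter. Candidates are pooled per neighborhood
    and accepted as loops only if the peak region is enriched against the
    horizontal, vertical and lower-left corner background regions of a
    donut-style window, each tested with a one-sided Wilcoxon rank-sum
    test. Includes a seeded synthetic Hi-C matrix generator with planted
    loops, evaluation utilities (anchor/protein-peak matching, loop-set
    intersection, aggregate loop pileups, two-proportion z-test) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
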