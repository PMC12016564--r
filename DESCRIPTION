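Package: diffgr
Title: Differential Genomic Regions at the TAD Level from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects differentially interacting genomic regions between two
    intra-chromosomal Hi-C contact maps at the scale of topologically
    associating domains (TADs).  Externally called TAD boundaries of the two
    samples are merged into a common partition of candidate regions, every
    potential (sub-)TAD is scored with a local stratum-adjusted correlation
    coefficient, and statistical significance is assessed with a
    nonparametric permutation test over random pseudo-TADs of matching size,
    followed by a similarity filter and Benjamini-Hochberg correction.
    Includes 2D mean-filter smoothing and Knight-Ruiz balancing of contact
    maps, readers for dense, triplet and cooler-style text formats, and a
    simulation framework with block-TAD structure, power-law distance decay,
    random-ligation noise and binomial coverage down-sampling for validation
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
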