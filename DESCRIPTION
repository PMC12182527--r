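Package: wildmap
Title: Simulated Crossing Designs for Association Mapping in Crop Wild
    Relative Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for comparing crossing designs that turn
    outcrossing crop wild relative populations (such as sea beet) into
    testcross mapping populations for genome-wide association mapping of
    quantitative traits.  Provides a synthetic founder-population generator
    calibrated to published wild beet summary statistics, origin-tagged
    meiosis and crossing primitives (selfing, backcrossing, doubled
    haploids), haplotype-based diversity subset selection, a geometric-series
    QTL plus infinitesimal-background trait model, a polygenic mixed-model
    score test with marker-based kinship, QTL-region calling with
    Benjamini-Hochberg control, and an experiment runner that estimates QTL
    detection power (true positive rate) and false detection rate across
    designs, heritabilities and trait architectures.
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
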