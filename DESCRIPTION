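Package: fmenr
Title: Functional Molecular Ecological Networks from Functional Gene Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for functional gene microarray (GeoChip-style)
    data from contrasting sample groups: signal preprocessing (signal-to-noise
    and prevalence filtering, ln(x+1) transformation, positive-control
    normalization, relative intensities), group richness/overlap statistics and
    per-category tests, permutation tests on dissimilarity matrices (PERMANOVA,
    ANOSIM, MRPP) with exact enumeration on small designs, random-matrix-theory
    based correlation network inference via the nearest-neighbour spacing
    distribution of unfolded eigenvalues, network topology with degree-preserving
    null ensembles, Zi/Pi node-role classification, and module eigengene to
    environment correlation. Includes a synthetic-data generator with planted
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    generics,
    ggplot2,
    igraph,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
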