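Package: peatmob
Title: Amplicon Bioinformatics and Methane Oxidation Analysis for Peat
    Methanotroph Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying methane-oxidizing
    bacteria (MOB) in peat soils from paired-end amplicon sequencing and
    closed-vial incubation data. Covers read merging, windowed phred
    filtering and primer trimming; dereplication, de novo and
    reference-based chimera screening, single-linkage (swarm-style, d = 1)
    OTU clustering, and reading-frame validation of protein-coding (pmoA)
    amplicons; reference-database trimming and best-global-alignment
    taxonomic assignment; community statistics (abundance thresholding,
    log normalization, site-conditioned partial redundancy analysis with
    permutation tests, IndVal indicator-species analysis, Kruskal-Wallis
    comparisons); neighbor-joining phylogenies with Jukes-Cantor distances
    and bootstrap support; and closed-vial methane accounting (ideal gas
    law, Henry's law, oxidation-rate regression, gravimetric water and
    soil organic matter). A synthetic-data module generates reference
    databases, communities, reads with planted artifacts, and gas time
    series with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
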