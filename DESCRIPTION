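Package: karyogc
Title: Chromosome-Class GC Heterogeneity Analysis from Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying intra-genomic GC heterogeneity from
    coding sequences: third-codon-position (GC3) and fourfold-degenerate-site
    (GC4) GC-content profiling with reading frames inferred by six-frame
    translated local alignment against reference proteins; classification of
    genes by karyotype size class (macrochromosome versus microchromosome);
    bimodality assessment of GC3 distributions by comparing one- and
    two-Gaussian histogram fits with the extra sum-of-squares F test and
    small-sample Akaike information criterion; rank tests, exact
    contingency tests and cross-species ortholog correlations; coupling of
    GC3 to the GC-content of surrounding non-coding regions; and
    FatiGO-style functional-category over-representation between
    chromosome-class gene lists. Seeded generators emulate the statistical
    structure of sauropsid cDNA-mapping studies so every analysis stage can
    be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
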