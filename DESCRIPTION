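Package: mitoscreen
Title: Comparative Circular Mitogenome Analysis and CMS Candidate ORF Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing two circular plant mitochondrial genomes to
    nominate candidate open reading frames for cytoplasmic male sterility
    (CMS). Implements circular-coordinate genome handling, six-frame ORF
    discovery with uniqueness, chimera, transmembrane and gene-adjacency
    screening, syntenic-block and unique-region decomposition with variant
    effect classification, exact repeat detection with block-junction
    association, repeat-mediated recombination modelling of master and
    subgenomic circles with long-read junction support, small quantitative
    utilities (2^-ddCt relative expression, marker tabulation,
    neighbor-joining trees, K2P distances), and a seeded synthetic
    mitogenome-pair generator with a ground-truth manifest so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    IRanges,
    ape,
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
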