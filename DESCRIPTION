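Package: ptmhotspots
Title: Family-Wide Prioritization of Post-Translational Modification Hotspots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to prioritize post-translational modification (PTM) sites
    by pooling modification evidence across a protein family alignment.
    Native PTM coordinates are mapped to alignment columns (modified
    alignment positions, MAPs), per-column features are computed
    (acceptor-residue conservation, total residue conservation, membership,
    PTM count, cluster PTM count, neighbor known-function count, interface
    residence), and each MAP is ranked by a multiplicative Integrative
    Score. Includes profile-to-profile alignment for merging sub-family
    alignments, region enrichment and conservation comparisons,
    protein-protein interface detection from atomic coordinates, projection
    of scores onto structures via the B-factor field, and synthetic-data
    generators with planted hotspots for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
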