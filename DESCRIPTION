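Package: chipcoloc
Title: Tiling ChIP Profile Processing and DSB Hotspot Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide tiling ChIP (ChIP-chip) occupancy profiles of the
    meiotic DSB machinery: Gaussian kernel smoothing, decile normalization, allele
    ratio profiles, automatic peak calling, and peak-to-hotspot colocalization
    statistics (nearest-edge distances, cumulative distance curves, a seeded
    random-placement Monte-Carlo null with percentile envelopes, and Fisher's exact
    tests). Includes a calibrated synthetic-data generator that emulates a
    16-chromosome yeast genome, a 3600-block DSB hotspot map, flanking axis sites,
    and three phospho-allele occupancy backgrounds, so that the full analysis stack
    can be exercised against known ground truth, plus a small protein-motif utility
    for [S/T]Q motifs and SQ/TQ cluster domains.
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
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
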