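Package: introsweep
Title: Copy-Number, Introgression and Selective-Sweep Scans for Polyploid Crop Resequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Window-based population-genomic scans for crop resequencing
    panels. Calls per-accession deletions and duplications from normalized
    read depth in sliding windows, merges them into cross-accession
    copy-number-variable regions, detects alien introgression segments from
    large deleted regions with an excess of divergent sites (one-sided Z
    test on per-window divergent-site ratios), computes windowed nucleotide
    diversity, Hudson Fst and dxy, scans for selective sweeps by the ln
    pi-ratio with empirical top-quantile thresholding, scores copy-number
    variants by the relative frequency difference between populations, and
    merges haplotype blocks with donor-population assignment. Ships a
    Balding-Nichols multi-population simulator with planted deletions,
    duplications, introgressions and sweeps so the whole pipeline can be
    exercised and benchmarked against a known truth set without any
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
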