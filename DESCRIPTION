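Package: nucshift
Title: Differential Promoter Nucleosome Occupancy from Paired-End MNase-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for in vivo nucleosome positioning analysis from
    aligned paired-end MNase-seq fragments: read-pair filtering on
    concordance, insert size and mismatch count; count-normalized smoothed
    fragment-midpoint occupancy tracks at 1-bp resolution; per-gene
    promoter-window occupancy-difference statistics anchored on +1
    nucleosome dyads, with blacklisting, ranking, baseline subtraction and
    top-N gene selection; +1-dyad-anchored heatmap matrices and average
    occupancy profiles. Includes a synthetic paired-end MNase-seq generator
    that emulates phased nucleosome arrays, promoter nucleosome-depleted
    regions and a conditional NDR-filling perturbation, so the whole
    pipeline runs and is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomeInfoDb,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
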