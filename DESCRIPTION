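Package: refstab
Title: Reference-Gene Screening and qRT-PCR Stability Ranking for
    Developmental Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate reference (housekeeping) genes from a
    stage-wise RNA-seq RPKM matrix by a filter cascade (expression,
    max/min ratio, coefficient of variation, abundance, transcript
    annotation), ranks candidate stability from qRT-PCR CT data with four
    independently implemented algorithms (delta-CT, geNorm, BestKeeper,
    NormFinder) plus a cross-method aggregate, validates chosen
    references by comparative-CT normalization of target genes against
    RNA-seq expression profiles, fits primer-efficiency dilution series,
    and simulates RPKM matrices and CT datasets with known ground truth
    for benchmarking. All user-facing functions take data frames and
    return tibbles.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
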