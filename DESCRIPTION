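Package: sagisou
Title: Lip Morphometrics and Microsatellite Population Genetics for the
    Egret Flower
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of lip (labellum) shape and
    microsatellite (SSR) diversity in fragmented populations of the egret
    flower, Habenaria radiata. Provides parametric synthetic generators
    for egret-shaped lip contours and diploid SSR genotype datasets with
    known ground truth; lip morphometrics (area, perimeter, dissection
    index, body and wing dimensions, serration counting) with normalized
    radar profiles; per-population diversity statistics (observed and
    unbiased expected heterozygosity, fixation index, exact
    Hardy-Weinberg tests, null-allele frequencies); Nei's standard
    genetic distance with neighbor-joining trees and locus-bootstrap
    supports; a Gibbs-sampling admixture model with ln P(D) scoring,
    Evanno delta-K model choice and cross-run label alignment; and
    readers/writers for the Genepop and STRUCTURE text formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    phangorn,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
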