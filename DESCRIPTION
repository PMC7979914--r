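Package: naiverep
Title: Clonotype Diversity and Developability Analysis of Antibody Library
    NGS Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of deep-sequenced naive antibody display libraries:
    Phred-based read quality filtering, simplified germline V/J assignment with
    e-value and identity acceptance thresholds, hierarchical CDR3 clonotyping
    that combines abundance filtering with Hamming-distance singleton rescue,
    Hill-number diversity and species-accumulation richness estimation by
    negative-exponential fitting, degenerate-primer specificity analysis with
    Ward minimum-variance clustering, and CDR biophysical profiling (net charge
    at pH 7, GRAVY hydropathy, length and V/J-pairing distributions,
    germline-scaffold developability summaries). Includes a synthetic
    repertoire generator emulating the heavy-tailed clonal structure of a
    single-donor library so the whole pipeline is testable without raw
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
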