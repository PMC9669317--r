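Package: ecotaxdb
Title: Ecosystem-Specific ASV-Resolved 16S rRNA Reference Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct and evaluate ecosystem-specific, amplicon sequence
    variant (ASV) resolved 16S rRNA gene reference databases with a complete
    seven-rank taxonomy. Full-length 16S sequences are trimmed to a primer
    window, dereplicated into full-length ASVs, annotated by identity-threshold
    taxonomy transfer from a universal reference database, and completed with
    systematically generated de novo placeholder names for lineages lacking
    official taxonomy. Evaluation tools cover sequence and taxonomy novelty,
    high-identity coverage of short-read amplicon data, bootstrap k-mer
    (SINTAX-style) classification rates, in-silico amplicon taxonomic
    resolution, and ecosystem-specific primer bias via position-weighted
    mismatch/gap scores. Seeded simulators provide reference sets, amplicon
    count tables, and primer-site perturbations with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
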