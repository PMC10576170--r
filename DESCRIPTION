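Package: synotip
Title: Reconcile Taxonomic Names in Comparative Data with Phylogeny Tip Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species names drift: comparative trait datasets and phylogenetic
    trees built at different times frequently label the same taxon with
    different binomials, so rows are silently dropped when data are matched to
    tree tips. synotip compiles candidate synonyms for target names from a
    synonym source (a local backbone table, or recorded taxonomy-service
    responses replayed through a uniform source contract), writes them as a
    ragged synonym CSV, and rewrites trait tables so their species names match
    the tip labels of a reference tree, with a full accounting of direct,
    recovered, ambiguous and unmatched names. An orthographic fallback handles
    Latin gender-ending variants (e.g. -um/-us) when a strict lookup fails,
    and a synthetic-taxonomy generator plants known synonym clouds so the
    whole pipeline is testable offline against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    readr,
    stringr,
    rlang,
    ape,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
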