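# synotip

Reconcile taxonomic names in comparative trait data with the tip labels of
a phylogenetic tree.

## The problem

Trait datasets and phylogenies are built years apart, under different
nomenclature: the tree says *Panthera_leo*, the dataset still says
*Felis_leo*, and that row is silently dropped when the data are matched to
tips. Across thousands of taxa — orthographic variants (*-um*/*-us*),
homotypic and heterotypic synonyms, genus transfers — the losses are large
and manual curation is slow.

synotip fixes this in two steps, treating the tree as the reference naming
frame:

1. **query** — for every tip label, compile its *synonym cloud* (accepted
   name + all known alternatives) from a synonym source, and write the
   clouds as a ragged CSV (row = query, syn₁, …, syn_k);
2. **reconcile** — look each trait label up in the clouds and, where it
   belongs to exactly one tip's cloud, write that tip's exact spelling into
   a new `tree_name` column, with a full report: `n_direct` (already a
   tip), `n_recovered` (swapped via a synonym), `n_ambiguous` (cloud
   reaches ≥ 2 tips — flagged, never guessed), `n_unmatched`. The four
   counts always partition the input, and non-name fields pass through
   byte-identical.

Comparison is case- and separator-insensitive set membership over normalized
keys (no fuzzy matching); when a strict lookup fails, a configurable table
of bidirectional Latin ending swaps (`um↔us`, `us↔a`, …) is tried and the
variant that succeeded is recorded. Homonyms are surfaced as ambiguous, with
all candidates listed. Synonym sources sit behind one contract
(`resolve(query) → synonym_record`): a local backbone TSV for deterministic
offline use, or recorded service responses replayed from JSON files. A
synthetic-taxonomy generator plants synonym clouds with known ground truth
so the whole pipeline is verifiable end to end without any download.

## Worked example

Bundled demo: a 10-species carnivore tree, a backbone with archaic synonyms,
and a trait table labeled with a mix of modern and archaic names.

```r
library(synotip)

backbone <- load_backbone(system.file("extdata", "demo_backbone.tsv", package = "synotip"))
tips     <- read_target_names(system.file("extdata", "demo_tree.nwk", package = "synotip"))
clouds   <- run_queries(tips, local_source(backbone), quiet = TRUE)
traits   <- read_trait_table(system.file("extdata", "demo_traits.csv", package = "synotip"))
result   <- reconcile_table(traits, build_match_index(clouds, tips))
glance(result)
#> # A tibble: 1 × 7
#>   n_input n_direct n_recovered n_ambiguous n_unmatched n_collisions prop_matched
#>     <int>    <int>       <int>       <int>       <int>        <int>        <dbl>
#> 1      10        4           6           0           0            0            1
head(result$table, 3)
#> # A tibble: 3 × 3
#>   species       mass_kg tree_name
#>   <chr>         <chr>   <chr>
#> 1 Felis_leo     190     Panthera_leo
#> 2 Panthera_onca 96      Panthera_onca
#> 3 Felis_rufus   9.6     Lynx_rufus
```

Four labels already matched tips; the six archaic labels (e.g. `Felis_leo`)
were recovered onto their modern tips, so no rows would be dropped from a
downstream comparative analysis. `tidy(result)` gives the per-name ledger,
`autoplot(result)` a bar chart of the breakdown, and `write_reconciled()`
emits the rewritten CSV plus report/ledger files.

A command-line entry point wraps the same functions
(`inst/cli/synotip.R`, subcommands `query | reconcile | synth`); see
`?cli_main`.

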