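---
title: "Reconciling taxonomic names between trait tables and phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling taxonomic names between trait tables and phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synotip)
library(ggplot2)
```

## The problem

Comparative analyses join two artifacts built at different times by
different communities: a phylogenetic tree, whose tip labels fix one naming
convention, and a trait table whose species labels have accumulated decades
of nomenclatural drift — orthographic variants (Latin gender endings such as
*-um*/*-us*), homotypic and heterotypic synonyms, genus transfers, and
outright archaisms (*Felis leo* for the modern *Panthera leo*). Every row
whose label fails to match a tip is silently dropped from the analysis, and
at the scale of thousands of taxa manual curation stops being feasible.

synotip treats the **tree as the reference naming frame**. The workflow has
two steps:

1. **Query.** For every tip label, compile a *synonym cloud* — the accepted
   name plus every alternative name a synonym source knows for that taxon —
   and collate the clouds into a ragged CSV (first field the query, the rest
   its synonyms).
2. **Reconcile.** Load the trait table, look each species label up in the
   clouds, and where a label belongs to exactly one tip's cloud, write that
   tip's exact spelling into a new `tree_name` column. Nothing else in the
   row is touched.

The match is set-membership over normalized keys, not fuzzy matching: a
label matches a tip if and only if some cloud links them. Edit-distance
approaches are a different tool for a different failure mode (typos), and
are deliberately out of scope.

## Name handling

All comparison happens on a *normalized key*: case-folded, with runs of
spaces/underscores collapsed, so `Felis_leo`, `felis leo` and `Felis  leo`
compare equal. Keys are only a comparison device — every output preserves
original spellings, and matched names use the tree's bytes exactly.

Names parse as genus + epithet (+ optional infraspecific). Trailing
authorship (`Panthera leo (Linnaeus, 1758)`) is stripped by keeping only the
leading alphabetic tokens; what was removed is retained in a `stripped`
field rather than discarded. A single-token name is malformed and is
reported, never silently dropped: in batch contexts it counts as unmatched.
Trinomials are parsed but matching is done at the binomial level by default,
since reference trees are nearly always binomial; `keep_infraspecific`
reverses this.

## The orthographic fallback

Strict lookups fail on Latin declension variants. When a query misses, each
*substitution rule* — a bidirectional epithet-ending swap — is applied in
rule-table order and the variants retried; the first hit is returned with
`via_variant` recording which spelling succeeded. The default table is

```{r}
default_substitution_rules()
```

Only the *um/us* swap (the *Orthriophis taeniurum* → *taeniurus* case) is
required by the classic failure mode; the other five are extensions covering
common gender/declension shifts. They are conservative — a rule only ever
rewrites the epithet's ending, never the genus — but any subset can be
supplied, and `no_substitution_rules()` disables the fallback entirely. We
chose not to ship broader ending tables by default: each extra rule enlarges
the probe set and with it the (small) risk of colliding with a genuinely
different epithet.

## Synonym sources

All backends implement one contract: `resolve(query)` returns a
`synonym_record` and never errors on a well-formed name — failure is
`matched = FALSE`. Three sources exist:

- `local_source(load_backbone(path))`: a tab-separated backbone of
  (accepted, synonym, status) rows with a reverse index from every name's
  key to its accepted name. This is the deterministic, offline path and the
  one the tests exercise everywhere. The index is an optimization only: a
  test asserts it agrees exactly with a brute-force scan of every entry.
- `replay_source(dir)`: recorded taxonomy-service responses, one JSON file
  per query named by its normalized key. This mirrors the two live query
  flows (a backbone-identity lookup returning canonical name + synonyms, and
  a search/dedupe/fetch/harvest flow) without network access or dependence
  on database state, which drifts over time. `harvest_names()` implements
  the exhaustive walk over the name-bearing fields of a fetched record;
  `dedupe_identifiers()` the first-kept identifier dedup between search and
  fetch.
- A live adapter would be a thin layer producing the same records; it is
  intentionally not part of the tested surface.

Homonyms — one name claimed by two accepted taxa — are **surfaced, never
resolved**: the backbone loader warns and registers the colliding key, and a
query hitting it comes back flagged `ambiguous` with all candidates listed.
Synonym status flags (homotypic / heterotypic / orthographic) are carried
through but never filter anything by default; which synonym is *right* is a
taxonomic judgment this tool does not make.

Batch resolution (`run_queries()`) is keyed and ordered by input position,
so output is byte-identical regardless of the `workers` setting (default 4,
kept as part of the batch contract for remote backends); the in-process
implementation is sequential, which on a single-core runner is also the
fastest choice. Duplicate input names collapse to one row with a message.

## Reconciliation semantics

`build_match_index()` unions, for every non-tip name, the set of tips
reachable through any cloud containing it:

- exactly one reachable tip → the name maps to it (`recovered`);
- two or more → `ambiguous`: the row is flagged and left for the user,
  because silently picking one would hide exactly the homonym errors a user
  most needs to see;
- a label that *is* a tip is always `direct`, even if some cloud also
  claims it elsewhere — direct identity overrides cloud membership;
- anything else is `unmatched`.

Several labels may legitimately resolve to one tip (lumping); all rows are
kept and the collision is reported. The matched name goes into a **new**
column by default, preserving provenance (`in_place = TRUE` opts into
overwriting). The unmatched sentinel is the empty string — `NA` is avoided
because it collides with a legitimate-looking name token — and is
configurable.

The `reconcile_result` carries the rewritten table and a report whose four
counts partition the input: `n_direct + n_recovered + n_ambiguous +
n_unmatched == n_input`, with row count, row order and all trait bytes
conserved. `tidy()` returns the per-name ledger, `glance()` the one-row
summary, `autoplot()` a bar chart of the breakdown. Reconciling an
already-reconciled matched column is the identity.

## The synthetic-data generator

Real benchmarks of this task need a multi-million-record occurrence dataset,
a published mega-tree, and live database state; none of that is available or
stable enough for a test suite. Instead, `generate_taxonomy()` builds a
taxonomy with *planted* drift and known ground truth:

- pseudo-Latin binomials from a fixed syllable inventory, epithets always
  ending in one of *-us -a -um -is -ii -ae* so the substitution rules apply;
- per species, a Poisson(`synonym_rate`) number of synonyms, each a genus
  transfer (flagged heterotypic), an ending swap via a real substitution
  rule (orthographic), or a fresh-epithet renaming (homotypic);
- a random binary tree over the accepted names (uniform(0,1] branch
  lengths — the tree is a label carrier, not an evolutionary model);
- a trait table, one row per species, whose label is the accepted name, a
  planted synonym (probability `p_trait_synonym`), or an orphan absent from
  the backbone (`p_trait_orphan`), with one standard-normal trait column.

Crucially the generator computes the **expected report at planting time**,
by bookkeeping, not by running the matcher — so end-to-end tests compare two
independent code paths, and the planted-recovery check is exact, not
statistical. Orphans must come back unmatched (zero false positives).
Homonym planting is off by default and used only to exercise the ambiguity
path deliberately.

Default conditions are 1000 species, 1.5 synonyms per species, 20% synonym
labels and 5% orphans — drift rates of the order seen when multi-decade
occurrence compilations meet a modern tree, at a size that keeps the full
benchmark under a minute on one core. The test suite uses 5–120 species per
fixture for breadth and 1000 for the headline run.

What the generator does **not** emulate: misspellings beyond the rule table,
rank changes, authorship inconsistencies inside the backbone itself, and the
sheer messiness of real service responses. Passing tests therefore
demonstrate the pipeline's bookkeeping and matching semantics, not the
coverage of any real database.

## Numerical and format choices

- Files are UTF-8; the synonym CSV is ragged and headerless (a header is
  meaningless over ragged rows), with within-row order fixed as canonical
  name, then current name, then remaining synonyms, so outputs diff cleanly.
- The ragged CSV is parsed line-by-line (a rectangular reader would pad or
  misfold rows); quoted fields with commas survive round-trips.
- Trait tables are read entirely as character so every non-name field
  passes through byte-identical; synthetic trait values are serialized with
  `%.15g`.
- All generation flows from a single integer seed through R's RNG; equal
  configs give byte-identical files.
- Backbone TSV serialization preserves first-appearance order of entries
  and synonyms, so write → read → write is byte-identical.

## A worked example

```{r}
backbone <- load_backbone(system.file("extdata", "demo_backbone.tsv",
                                      package = "synotip"))
tips <- read_target_names(system.file("extdata", "demo_tree.nwk",
                                      package = "synotip"))
clouds <- run_queries(tips, local_source(backbone), quiet = TRUE)
traits <- read_trait_table(system.file("extdata", "demo_traits.csv",
                                       package = "synotip"))
result <- reconcile_table(traits, build_match_index(clouds, tips))
glance(result)
tidy(result)
autoplot(result)
```

## Limitations

- Matching is exact over clouds plus the rule table; typos outside the rule
  endings stay unmatched by design.
- The tool reports ambiguity and lumping; it does not adjudicate them.
- A name that is absent from the synonym source simply cannot be recovered;
  recall is bounded by the source's coverage.
- The replay source reflects whatever was recorded; a drifted live database
  will answer differently.
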