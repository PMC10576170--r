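# Shared fixtures and independent oracles for the test suite.

# write a backbone TSV from (accepted, synonym, status) triples
write_backbone_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  lines <- c("accepted_name\tsynonym\tstatus",
             vapply(rows, paste, "", collapse = "\t"))
  writeLines(lines, path)
  path
}

# the one-row lion backbone: the motivating archaic-name case
lion_backbone <- function() {
  write_backbone_tsv(list(c("Panthera leo", "Felis leo", "heterotypic")))
}

# Independent oracle: literal list-of-lists reconciliation. For each trait
# name, scan every synonym row start to finish; a name that is itself a tip
# stays put; otherwise the tips reachable from any row whose cloud contains
# the name decide its fate (one tip = swap, several = ambiguous, none =
# unmatched). No index, no precomputation.
brute_force_ledger <- function(trait_names, synonyms, tips) {
  tip_keys <- normalize_key(tips)
  out <- lapply(trait_names, function(nm) {
    key <- normalize_key(nm)
    if (key %in% tip_keys) {
      return(list(status = "direct", tip = tips[match(key, tip_keys)]))
    }
    reachable <- character(0)
    if (!is.null(synonyms) && nrow(synonyms) > 0) {
      for (i in seq_len(nrow(synonyms))) {
        cloud_keys <- normalize_key(c(synonyms$query[i], synonyms$synonyms[[i]]))
        if (key %in% cloud_keys) {
          reachable <- union(reachable, tips[tip_keys %in% cloud_keys])
        }
      }
    }
    if (length(reachable) == 1L) {
      list(status = "recovered", tip = reachable)
    } else if (length(reachable) >= 2L) {
      list(status = "ambiguous", tip = NA_character_)
    } else {
      list(status = "unmatched", tip = NA_character_)
    }
  })
  tibble::tibble(
    original = trait_names,
    status = vapply(out, `[[`, "", "status"),
    tip = vapply(out, `[[`, "", "tip")
  )
}

# full pipeline on a synthetic taxonomy: query tips, index, reconcile
run_synth_pipeline <- function(cfg) {
  tax <- generate_taxonomy(cfg)
  tree <- make_tree(tax$truth, seed = cfg$seed)
  tt <- make_trait_table(tax$truth, cfg)
  tab <- run_queries(tree$tip.label, local_source(tax$backbone), quiet = TRUE)
  idx <- build_match_index(tab, tree$tip.label)
  res <- reconcile_table(tt$traits, idx)
  list(tax = tax, tree = tree, traits = tt$traits, expected = tt$expected,
       labels = tt$labels, synonyms = tab, index = idx, result = res)
}
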