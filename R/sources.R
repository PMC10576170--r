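#' Construct a synonym record
#'
#' The unit result of any synonym source: one query's resolved identity. Used
#' by backends and collated into synonym tables by [run_queries()].
#'
#' @param query Raw input name string, preserved verbatim.
#' @param matched Did the source resolve the name?
#' @param canonical Accepted name per the source (`NA` when unmatched).
#' @param current Currently-used name per the source (`NA` when unmatched).
#' @param synonyms Character vector of other names in the taxon's cloud,
#'   canonical-spelling first; deduplicated under [normalize_key()] and never
#'   containing the query's own key.
#' @param source Backend identifier, e.g. `"local"`.
#' @param via_variant Orthographic variant that succeeded when the verbatim
#'   query failed (`NA` otherwise).
#' @param ambiguous Homonym flag: the query key hits more than one accepted
#'   name; no single resolution is chosen.
#' @param candidates Accepted names competing for an ambiguous key.
#' @param retryable Transport-failure flag for remote backends.
#' @return One-row tibble of class `synonym_record`.
#' @export
synonym_record <- function(query, matched = FALSE, canonical = NA_character_,
                           current = NA_character_, synonyms = character(),
                           source = NA_character_, via_variant = NA_character_,
                           ambiguous = FALSE, candidates = character(),
                           retryable = FALSE) {
  if (!matched) {
    canonical <- NA_character_
    current <- NA_character_
    synonyms <- character()
  } else {
    qkey <- normalize_key(query)
    synonyms <- synonyms[normalize_key(synonyms) != qkey]
    synonyms <- synonyms[!duplicated(normalize_key(synonyms))]
  }
  out <- tibble::tibble(
    query = query, matched = matched, canonical = canonical,
    current = current, synonyms = list(synonyms), source = source,
    via_variant = via_variant, ambiguous = ambiguous,
    candidates = list(candidates), retryable = retryable
  )
  class(out) <- c("synonym_record", class(out))
  out
}

#' Wrap a backbone table as a synonym source
#'
#' The source contract is a single deterministic operation
#' `resolve(query) -> synonym_record` that never errors on a well-formed
#' name; failure is expressed as `matched = FALSE`. All backends (local
#' backbone, recorded-response replay, and any live adapter) present this
#' same surface, so the query and reconcile layers are backend-agnostic.
#'
#' @param table A `backbone_table` from [load_backbone()].
#' @return A `synonym_source` object.
#' @export
local_source <- function(table) {
  stopifnot(inherits(table, "backbone_table"))
  new_source("local", function(query) resolve_local(table, query))
}

new_source <- function(name, resolve) {
  structure(list(name = name, resolve = resolve), class = "synonym_source")
}

#' @export
print.synonym_source <- function(x, ...) {
  cat(sprintf("<synonym_source> backend '%s'\n", x$name))
  invisible(x)
}

#' Replay recorded taxonomy-service responses as a synonym source
#'
#' Deterministic stand-in for the live GBIF/NCBI query flows: one JSON file
#' per query, stored under `dir` and named by the query's normalized key with
#' spaces replaced by underscores (e.g. `felis_leo.json`). Each file holds
#' the fields of a resolved record: `matched`, and when matched `canonical`,
#' `current`, `synonyms`. For NCBI-style raw records, store the nested record
#' under a `record` field instead and the names are harvested with
#' [harvest_names()] at replay time. Queries with no fixture file are
#' unmatched. Live-network adapters are out of scope for the offline test
#' path; recording a response once makes the flow replayable forever,
#' independent of database state.
#'
#' @param dir Fixtures directory.
#' @param name Backend identifier for provenance, default `"replay"`.
#' @return A `synonym_source`.
#' @export
replay_source <- function(dir, name = "replay") {
  if (!dir.exists(dir)) stop("fixtures directory not found: ", dir, call. = FALSE)
  force(name)
  new_source(name, function(query) {
    key <- normalize_key(query)
    path <- file.path(dir, paste0(gsub(" ", "_", key, fixed = TRUE), ".json"))
    if (!file.exists(path)) return(synonym_record(query, source = name))
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(rec$record)) {
      found <- harvest_names(rec$record)
      if (length(found) == 0L) return(synonym_record(query, source = name))
      canonical <- if (!is.null(rec$canonical)) rec$canonical else found[1]
      return(synonym_record(query, matched = TRUE, canonical = canonical,
                            current = canonical, synonyms = found,
                            source = name))
    }
    if (!isTRUE(rec$matched)) return(synonym_record(query, source = name))
    synonym_record(query, matched = TRUE,
                   canonical = rec$canonical %||% NA_character_,
                   current = rec$current %||% rec$canonical %||% NA_character_,
                   synonyms = as.character(rec$synonyms %||% character()),
                   source = name)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve with orthographic-variant fallback
#'
#' Tries the query verbatim against a source; if unmatched (and not flagged
#' ambiguous), tries each variant from [generate_variants()] in deterministic
#' rule order and returns the first match with `via_variant` recording the
#' variant that succeeded. If all variants fail (or the query does not parse
#' as a binomial, or the rule table is empty) the record is unmatched.
#'
#' @param source A `synonym_source`.
#' @param query Name string.
#' @param rules Substitution rules tibble; [default_substitution_rules()] by
#'   default, [no_substitution_rules()] disables the fallback.
#' @return One-row `synonym_record` tibble.
#' @export
resolve_with_fallback <- function(source, query,
                                  rules = default_substitution_rules()) {
  stopifnot(inherits(source, "synonym_source"))
  rec <- source$resolve(query)
  if (rec$matched || rec$ambiguous) return(rec)
  if (!is_parseable_taxon(query)) return(rec)
  sep <- if (grepl("_", query, fixed = TRUE)) "_" else " "
  variants <- generate_variants(parse_taxon(query), rules)
  for (v in format_taxon(variants, separator = sep)) {
    vrec <- source$resolve(v)
    if (vrec$ambiguous) {
      vrec$query <- query
      vrec$via_variant <- v
      return(vrec)
    }
    if (vrec$matched) {
      out <- synonym_record(query, matched = TRUE, canonical = vrec$canonical,
                            current = vrec$current,
                            synonyms = c(vrec$synonyms[[1]], v),
                            source = vrec$source, via_variant = v)
      return(out)
    }
  }
  rec
}

#' Remove duplicate backend identifiers, order preserved
#'
#' Identifier lists returned by a search step can contain duplicates; they
#' are removed keeping the first occurrence before any batch fetch.
#'
#' @param ids Vector of identifiers.
#' @return `ids` with duplicates removed, first occurrence kept.
#' @export
#' @examples
#' dedupe_identifiers(c(7, 3, 7, 7, 1)) # 7 3 1
dedupe_identifiers <- function(ids) {
  ids[!duplicated(ids)]
}

#' Harvest all names from a nested taxonomy record
#'
#' Exhaustively searches the name-bearing fields of a parsed service record
#' (the structure the NCBI Taxonomy efetch XML parses into): `ScientificName`
#' / `Name` strings anywhere in the structure, everything under `OtherNames`
#' (synonyms, GenBank synonyms, common names, and `Name` sub-records with a
#' `DispName`). All strings found are returned in encounter order,
#' deduplicated under [normalize_key()] with original spellings preserved.
#' Missing fields contribute nothing; a record with no name fields yields an
#' empty vector.
#'
#' @param entry A nested list (parsed record). Fixtures may construct it
#'   directly.
#' @param fields Field names treated as name-bearing.
#' @param exclude Field names that annotate rather than name (never
#'   harvested, even inside a name-bearing field).
#' @return Character vector of unique names, encounter order.
#' @export
harvest_names <- function(entry,
                          fields = c("ScientificName", "Name", "OtherNames",
                                     "Synonym", "GenbankSynonym", "DispName",
                                     "EquivalentName", "CommonName",
                                     "synonym", "name"),
                          exclude = c("ClassCDE", "UniqueName", "TaxId",
                                      "Rank", "Division")) {
  found <- character()
  walk <- function(node, harvesting) {
    if (is.list(node)) {
      nm <- names(node)
      for (i in seq_along(node)) {
        named <- !is.null(nm) && nzchar(nm[i])
        if (named && nm[i] %in% exclude) next
        child_harvesting <- harvesting || (named && nm[i] %in% fields)
        walk(node[[i]], child_harvesting)
      }
    } else if (is.character(node) && harvesting) {
      found <<- c(found, node)
    }
  }
  walk(entry, FALSE)
  found <- found[nzchar(trimws(found))]
  found[!duplicated(normalize_key(found))]
}
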