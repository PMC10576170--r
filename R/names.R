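#' Parse species names into genus / epithet / infraspecific parts
#'
#' Splits raw name strings on whitespace or underscores into a genus, a
#' specific epithet, and (optionally) an infraspecific epithet. Trailing
#' authorship strings such as `"(Linnaeus, 1758)"` are stripped: only leading
#' tokens made purely of letters (and hyphens) are kept, and anything dropped
#' is recorded in the `stripped` column. The original input is preserved
#' verbatim in `raw`.
#'
#' @param raw Character vector of species names, e.g. `"Panthera_leo"` or
#'   `"Orthriophis taeniurus"`.
#' @param collapse_trinomials If `TRUE` (default) a third (infraspecific)
#'   token is parsed but excluded from the matching form returned by
#'   [format_taxon()]; set `FALSE` to keep trinomials intact.
#'
#' @return A tibble with one row per input and columns `genus`, `epithet`,
#'   `infraspecific` (`NA` when absent), `raw`, and `stripped` (authorship or
#'   other trailing text that was removed, `NA` when nothing was stripped).
#' @details A name with fewer than two usable tokens (empty input, or a
#'   uninomial such as `"Panthera"`) is malformed: by default this is an
#'   error, so that bad rows are surfaced rather than silently dropped. Use
#'   [is_parseable_taxon()] to pre-screen when malformed rows must be counted
#'   instead.
#' @export
#' @examples
#' parse_taxon(c("Panthera_leo", "Orthriophis taeniurus"))
parse_taxon <- function(raw, collapse_trinomials = TRUE) {
  stopifnot(is.character(raw))
  rows <- lapply(raw, parse_taxon_one)
  bad <- vapply(rows, is.null, logical(1))
  if (any(bad)) {
    stop("malformed species name (need at least genus and epithet): ",
         paste(sprintf("'%s'", raw[bad]), collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (collapse_trinomials) out else out
}

# Internal single-name parser; returns NULL for malformed input.
parse_taxon_one <- function(x) {
  if (is.na(x)) return(NULL)
  tokens <- strsplit(trimws(x), "[ _]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  # keep leading purely-alphabetic tokens; authorship ("(Linnaeus, 1758)")
  # and year suffixes fail the pattern and end the name
  ok <- grepl("^[A-Za-z][A-Za-z-]*$", tokens)
  n_keep <- if (any(!ok)) which(!ok)[1] - 1L else length(tokens)
  n_keep <- min(n_keep, 3L)
  if (n_keep < 2L) return(NULL)
  kept <- tokens[seq_len(n_keep)]
  stripped <- if (n_keep < length(tokens)) {
    paste(tokens[-seq_len(n_keep)], collapse = " ")
  } else {
    NA_character_
  }
  genus <- paste0(toupper(substr(kept[1], 1, 1)), tolower(substr(kept[1], 2, nchar(kept[1]))))
  tibble::tibble(
    genus = genus,
    epithet = tolower(kept[2]),
    infraspecific = if (n_keep >= 3L) tolower(kept[3]) else NA_character_,
    raw = x,
    stripped = stripped
  )
}

#' Test whether names parse as binomials/trinomials
#'
#' @param raw Character vector of candidate names.
#' @return Logical vector: `TRUE` where [parse_taxon()] would succeed.
#' @export
is_parseable_taxon <- function(raw) {
  vapply(raw, function(x) !is.null(parse_taxon_one(x)), logical(1),
         USE.NAMES = FALSE)
}

#' Normalized comparison key for species names
#'
#' Comparison between datasets, backbones and tree tips is done on a
#' case-folded key in which runs of spaces and/or underscores collapse to a
#' single space, so `"Felis_leo"`, `"felis leo"` and `"Felis  leo"` compare
#' equal. Normalization is idempotent. Unparseable input falls back to folding
#' the whole string; it never errors.
#'
#' @param x Character vector of names (or a tibble from [parse_taxon()], in
#'   which case the matching form is keyed).
#' @return Character vector of keys, same length as the input.
#' @export
#' @examples
#' normalize_key("Felis_leo") == normalize_key("felis  LEO")
normalize_key <- function(x) {
  if (is.data.frame(x)) x <- format_taxon(x, separator = " ")
  stopifnot(is.character(x))
  tolower(gsub("[ _]+", " ", trimws(x)))
}

#' Format parsed names back into strings
#'
#' Joins genus, epithet and (optionally) the infraspecific epithet with a
#' separator. For well-formed names `parse_taxon(format_taxon(n))` recovers
#' the same parts (round-trip).
#'
#' @param taxa Tibble from [parse_taxon()].
#' @param separator Token separator, `"_"` (default) or `" "`.
#' @param keep_infraspecific Include the third token when present? Default
#'   `FALSE`: matching is done at the binomial level.
#' @return Character vector of formatted names.
#' @export
format_taxon <- function(taxa, separator = "_", keep_infraspecific = FALSE) {
  stopifnot(is.data.frame(taxa), all(c("genus", "epithet") %in% names(taxa)))
  out <- paste(taxa$genus, taxa$epithet, sep = separator)
  if (keep_infraspecific && "infraspecific" %in% names(taxa)) {
    has3 <- !is.na(taxa$infraspecific)
    out[has3] <- paste(out[has3], taxa$infraspecific[has3], sep = separator)
  }
  out
}

#' Default epithet-ending substitution rules
#'
#' Bidirectional Latin gender/declension ending swaps applied to the specific
#' epithet when a strict lookup fails. Only the um/us swap is required for the
#' classic *Orthriophis taeniurum* / *taeniurus* case; the remaining rules are
#' documented extensions covering common declension shifts and can be disabled
#' by passing a subset (or an empty tibble) to the functions that take
#' `rules`.
#'
#' @return A tibble with columns `suffix_a`, `suffix_b`.
#' @export
#' @examples
#' default_substitution_rules()
default_substitution_rules <- function() {
  tibble::tibble(
    suffix_a = c("um", "us", "um", "is", "ii", "ae"),
    suffix_b = c("us", "a",  "a",  "e",  "i",  "a")
  )
}

#' An empty substitution-rule table (fallback disabled)
#' @return A zero-row rules tibble.
#' @export
no_substitution_rules <- function() {
  tibble::tibble(suffix_a = character(), suffix_b = character())
}

# swap `from`-ending for `to` on an epithet, or NA if it doesn't apply;
# the whole epithet must be longer than the suffix (never empty the stem)
swap_suffix <- function(epithet, from, to) {
  n <- nchar(epithet)
  k <- nchar(from)
  if (n <= k || substr(epithet, n - k + 1, n) != from) return(NA_character_)
  paste0(substr(epithet, 1, n - k), to)
}

#' Generate orthographic variants of a species name
#'
#' Applies each substitution rule to the epithet ending, in both directions,
#' in rule-table order (a-to-b before b-to-a within a rule). The genus is
#' never altered, the input name itself is excluded, and duplicates are
#' removed keeping first occurrence, so the result order is deterministic.
#'
#' @param taxon A single-row tibble from [parse_taxon()] or a single name
#'   string.
#' @param rules Rules tibble, default [default_substitution_rules()]. An
#'   empty rule table yields an empty result for every input.
#' @return Tibble of variant names (columns as [parse_taxon()]), zero rows if
#'   no rule ending matches.
#' @export
#' @examples
#' generate_variants("Orthriophis_taeniurum")$epithet # contains "taeniurus"
generate_variants <- function(taxon, rules = default_substitution_rules()) {
  if (is.character(taxon)) taxon <- parse_taxon(taxon)
  stopifnot(nrow(taxon) == 1L)
  eps <- character(0)
  for (i in seq_len(nrow(rules))) {
    eps <- c(eps,
             swap_suffix(taxon$epithet, rules$suffix_a[i], rules$suffix_b[i]),
             swap_suffix(taxon$epithet, rules$suffix_b[i], rules$suffix_a[i]))
  }
  eps <- eps[!is.na(eps)]
  eps <- eps[eps != taxon$epithet]
  eps <- eps[!duplicated(eps)]
  if (length(eps) == 0L) {
    return(tibble::tibble(genus = character(), epithet = character(),
                          infraspecific = character(), raw = character(),
                          stripped = character()))
  }
  tibble::tibble(
    genus = taxon$genus,
    epithet = eps,
    infraspecific = NA_character_,
    raw = paste(taxon$genus, eps, sep = "_"),
    stripped = NA_character_
  )
}
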