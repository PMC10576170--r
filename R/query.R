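#' Read target species names from a list file or a Newick tree
#'
#' Newick input (detected by extension `.nwk`, `.newick`, `.tre`, `.tree`,
#' `.phy`, or by a leading `(`) yields the leaf labels in tree order, with
#' quoted labels unquoted. Text/CSV input yields first-column values, in
#' order, skipping blank lines; a first row that does not parse as a binomial
#' (e.g. a `species` header) is treated as a header and skipped.
#'
#' @param path Input file.
#' @return Character vector of target names, order preserved.
#' @export
read_target_names <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop("empty input: ", path, call. = FALSE)
  is_newick <- grepl("\\.(nwk|newick|tre|tree|phy)$", path, ignore.case = TRUE) ||
    startsWith(trimws(nonblank[1]), "(")
  if (is_newick) {
    tree <- tryCatch(ape::read.tree(path),
                     error = function(e) stop("malformed Newick in ", path, ": ",
                                              conditionMessage(e), call. = FALSE))
    if (is.null(tree)) stop("malformed Newick in ", path, call. = FALSE)
    labels <- tree$tip.label
    if (length(labels) == 0L) stop("empty input: no tips in ", path, call. = FALSE)
    # strip residual quoting around labels
    return(gsub("^['\"]|['\"]$", "", labels))
  }
  first_col <- vapply(strsplit(nonblank, ",", fixed = TRUE), `[`, "", 1L)
  first_col <- gsub('^"|"$', "", trimws(first_col))
  if (length(first_col) > 1L && !is_parseable_taxon(first_col[1])) {
    first_col <- first_col[-1L]
  }
  if (length(first_col) == 0L) stop("empty input: ", path, call. = FALSE)
  first_col
}

#' Batch-resolve a name list into a synonym table
#'
#' One row per distinct input name (duplicates under [normalize_key()]
#' collapse to the first occurrence, with a message), each produced by
#' [resolve_with_fallback()] against the source. Row order equals input
#' order regardless of `workers`: results are keyed by input position, so
#' output is byte-identical for any worker count. Per-name failures are never
#' fatal — unresolved queries yield unmatched rows.
#'
#' @param names Character vector of query names (non-empty).
#' @param source A `synonym_source`.
#' @param workers Worker count (>= 1, default 4). Part of the batch contract
#'   for remote backends; resolution order never affects output.
#' @param rules Substitution rules for the orthographic fallback.
#' @param quiet Suppress the summary message?
#' @return A `synonym_table`: tibble with one row per distinct query and the
#'   columns of [synonym_record()], plus attributes `source` and `rules`.
#' @export
run_queries <- function(names, source, workers = 4,
                        rules = default_substitution_rules(), quiet = FALSE) {
  stopifnot(is.character(names), inherits(source, "synonym_source"))
  if (length(names) == 0L) stop("empty name list", call. = FALSE)
  if (!is.numeric(workers) || workers < 1) stop("workers must be >= 1", call. = FALSE)
  dup <- duplicated(normalize_key(names))
  if (any(dup) && !quiet) {
    message(sum(dup), " duplicate input name(s) collapsed: ",
            paste(unique(names[dup]), collapse = ", "))
  }
  names <- names[!dup]
  rows <- purrr::map(names, function(q) {
    tryCatch(resolve_with_fallback(source, q, rules),
             error = function(e) {
               r <- synonym_record(q, source = source$name, retryable = TRUE)
               r
             })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("synonym_table", class(out))
  attr(out, "source") <- source$name
  attr(out, "rules") <- rules
  if (!quiet) {
    message(sprintf("queried %d name(s): %d matched (%d via variant), %d unmatched, %d ambiguous",
                    nrow(out), sum(out$matched), sum(!is.na(out$via_variant)),
                    sum(!out$matched & !out$ambiguous), sum(out$ambiguous)))
  }
  out
}

# quote a field for CSV output only when needed
csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Write a synonym table as ragged CSV
#'
#' The interchange format between the query and reconcile steps: UTF-8, no
#' header; row i is `query_i, syn_1, ..., syn_k` with the record's synonyms
#' in order (canonical name first, then the current name when distinct, then
#' the remaining synonyms — the order the records carry). Unmatched queries
#' produce a single-field row. Output is byte-stable given a fixed table.
#'
#' @param table A `synonym_table` (or any tibble with `query` and a
#'   `synonyms` list column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synonym_csv <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  lines <- purrr::map_chr(seq_len(nrow(table)), function(i) {
    fields <- c(table$query[i], table$synonyms[[i]])
    paste(csv_quote(fields), collapse = ",")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a ragged synonym CSV
#'
#' Parses the list-of-lists synonym format written by [write_synonym_csv()]:
#' first field of each row is the query, remaining fields its synonyms.
#' Quoted fields (commas preserved) are handled; blank lines are skipped with
#' a warning.
#'
#' @param path Input path.
#' @return A `synonym_table` tibble with columns `query`, `matched`,
#'   `synonyms` (matched is inferred: any synonym present).
#' @export
read_synonym_csv <- function(path) {
  if (!file.exists(path)) stop("synonym file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop("empty synonym file: ", path, call. = FALSE)
  }
  if (any(!nzchar(trimws(lines)))) {
    warning("blank line(s) skipped in ", path, call. = FALSE)
    lines <- lines[nzchar(trimws(lines))]
  }
  # rows are ragged, so parse line by line (a rectangular reader would pad
  # or fold fields based on the width of the first rows)
  rows <- purrr::map(lines, function(line) {
    scan(text = line, what = character(), sep = ",", quote = '"',
         quiet = TRUE, strip.white = FALSE)
  })
  out <- tibble::tibble(
    query = vapply(rows, `[`, "", 1L),
    matched = lengths(rows) > 1L,
    synonyms = lapply(rows, function(f) f[-1L])
  )
  class(out) <- c("synonym_table", class(out))
  out
}
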