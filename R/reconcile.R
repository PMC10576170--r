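#' Build a name-to-tip match index from a synonym table
#'
#' The synonym rows are a list of lists: each row is one name cloud (the
#' query plus every synonym found for it). For each cloud, the tips of the
#' reference tree reachable from any member are collected; if exactly one tip
#' is reachable, every non-tip member of the cloud maps to it. A name whose
#' clouds reach two or more distinct tips is ambiguous — it is flagged, not
#' resolved. Tip labels always map to themselves (direct identity overrides
#' any cloud membership), and all comparison happens on [normalize_key()]
#' while the tree's original tip spelling is what the index returns.
#'
#' @param synonyms A `synonym_table` (from [run_queries()] or
#'   [read_synonym_csv()]); may be `NULL` or zero-row for the identity-on-tips
#'   index.
#' @param tips Character vector of tip labels (non-empty), e.g. from
#'   [read_target_names()] on a Newick file.
#' @return A `match_index` object: mapping key -> tip label, the ambiguity
#'   set, and the tip self-map.
#' @export
build_match_index <- function(synonyms, tips) {
  stopifnot(is.character(tips), length(tips) > 0L)
  tip_keys <- normalize_key(tips)
  if (anyDuplicated(tip_keys)) {
    warning("tip labels identical under normalization; first spelling kept",
            call. = FALSE)
    tips <- tips[!duplicated(tip_keys)]
    tip_keys <- tip_keys[!duplicated(tip_keys)]
  }
  tip_map <- stats::setNames(tips, tip_keys)

  # candidate tips per non-tip key, unioned across all clouds containing it
  cand <- new.env(parent = emptyenv())
  if (!is.null(synonyms) && nrow(synonyms) > 0L) {
    for (i in seq_len(nrow(synonyms))) {
      cloud <- unique(c(synonyms$query[i], synonyms$synonyms[[i]]))
      keys <- unique(normalize_key(cloud))
      hit <- unique(tip_map[keys[keys %in% names(tip_map)]])
      if (length(hit) == 0L) next
      for (k in keys[!keys %in% names(tip_map)]) {
        cand[[k]] <- unique(c(cand[[k]], hit))
      }
    }
  }
  keys <- ls(cand)
  n_hit <- vapply(keys, function(k) length(cand[[k]]), integer(1))
  map <- vapply(keys[n_hit == 1L], function(k) cand[[k]], "")
  structure(
    list(map = map, ambiguous = keys[n_hit >= 2L], tips = tip_map),
    class = "match_index"
  )
}

#' @export
print.match_index <- function(x, ...) {
  cat(sprintf("<match_index> %d tip(s), %d synonym mapping(s), %d ambiguous key(s)\n",
              length(x$tips), length(x$map), length(x$ambiguous)))
  invisible(x)
}

classify_key <- function(key, index) {
  dplyr::case_when(
    key %in% names(index$tips) ~ "direct",
    key %in% index$ambiguous ~ "ambiguous",
    key %in% names(index$map) ~ "recovered",
    TRUE ~ "unmatched"
  )
}

#' Reconcile a trait table against phylogeny tips
#'
#' Rewrites the species names of a comparative table so they match the tip
#' labels of a reference tree. Each row's name (first column) is classified:
#' `direct` (already a tip), `recovered` (swapped in via a synonym cloud),
#' `ambiguous` (its clouds reach two or more tips — left for the user's
#' taxonomic judgment), or `unmatched`. The matched name is written to a new
#' column (default `tree_name`) using the tree's exact tip spelling; the
#' sentinel (default empty) marks ambiguous/unmatched rows. Row order, row
#' count and every non-name field pass through untouched, and reconciling an
#' already-reconciled matched column is the identity.
#'
#' @param traits Tibble whose first column holds underscore-separated
#'   binomial species names; remaining columns are opaque trait values.
#' @param index A `match_index` from [build_match_index()].
#' @param match_col Name of the appended matched-name column.
#' @param in_place Overwrite the name column for matched rows instead of
#'   appending a column (provenance is then lost; default `FALSE`).
#' @param sentinel Value written for ambiguous/unmatched rows.
#' @return A `reconcile_result`: list with `$table` (the rewritten tibble)
#'   and `$report` (a `reconcile_report`). [generics::tidy()] gives the
#'   per-name ledger, [generics::glance()] the one-row summary.
#' @export
reconcile_table <- function(traits, index, match_col = "tree_name",
                            in_place = FALSE, sentinel = "") {
  stopifnot(is.data.frame(traits), nrow(traits) > 0L,
            inherits(index, "match_index"))
  traits <- tibble::as_tibble(traits)
  original <- as.character(traits[[1L]])
  key <- normalize_key(original)
  status <- classify_key(key, index)
  malformed <- !is_parseable_taxon(original)
  if (any(malformed & status == "unmatched")) {
    message(sum(malformed & status == "unmatched"),
            " malformed name row(s) counted unmatched")
  }
  tip <- dplyr::case_when(
    status == "direct" ~ unname(index$tips[key]),
    status == "recovered" ~ unname(index$map[key]),
    TRUE ~ NA_character_
  )
  ledger <- tibble::tibble(original = original, key = key,
                           status = status, tip = tip)
  out <- traits
  if (in_place) {
    out[[1L]] <- ifelse(is.na(tip), original, tip)
  } else {
    out[[match_col]] <- ifelse(is.na(tip), sentinel, tip)
  }
  matched_ledger <- ledger[!is.na(ledger$tip), , drop = FALSE]
  coll <- matched_ledger |>
    dplyr::distinct(.data$key, .data$tip) |>
    dplyr::count(.data$tip, name = "n_names") |>
    dplyr::filter(.data$n_names > 1L)
  report <- structure(
    list(
      n_input = nrow(traits),
      n_direct = sum(status == "direct"),
      n_recovered = sum(status == "recovered"),
      n_ambiguous = sum(status == "ambiguous"),
      n_unmatched = sum(status == "unmatched"),
      collisions = coll,
      ledger = ledger
    ),
    class = "reconcile_report"
  )
  structure(list(table = out, report = report), class = "reconcile_result")
}

#' @export
print.reconcile_report <- function(x, ...) {
  cat(sprintf(
    "<reconcile_report> %d row(s): %d direct, %d recovered, %d ambiguous, %d unmatched; %d tip collision(s)\n",
    x$n_input, x$n_direct, x$n_recovered, x$n_ambiguous, x$n_unmatched,
    nrow(x$collisions)))
  invisible(x)
}

#' @export
print.reconcile_result <- function(x, ...) {
  print(x$report)
  print(x$table)
  invisible(x)
}

#' Tidy the per-name reconciliation ledger
#'
#' @param x A `reconcile_result`.
#' @param ... Unused.
#' @return Tibble with columns `original`, `key`, `status`
#'   (direct/recovered/ambiguous/unmatched) and `tip` (`NA` when no tip was
#'   assigned).
#' @exportS3Method generics::tidy
tidy.reconcile_result <- function(x, ...) x$report$ledger

#' One-row summary of a reconciliation
#'
#' @param x A `reconcile_result`.
#' @param ... Unused.
#' @return One-row tibble: `n_input`, `n_direct`, `n_recovered`,
#'   `n_ambiguous`, `n_unmatched`, `n_collisions`, `prop_matched`.
#' @exportS3Method generics::glance
glance.reconcile_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_input = r$n_input, n_direct = r$n_direct, n_recovered = r$n_recovered,
    n_ambiguous = r$n_ambiguous, n_unmatched = r$n_unmatched,
    n_collisions = nrow(r$collisions),
    prop_matched = (r$n_direct + r$n_recovered) / r$n_input
  )
}

#' Plot the reconciliation outcome breakdown
#'
#' Bar chart of row counts by match status — the at-a-glance view of how much
#' data a synonym pass preserved that direct matching would have dropped.
#'
#' @param object A `reconcile_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.reconcile_result <- function(object, ...) {
  r <- object$report
  df <- tibble::tibble(
    status = factor(c("direct", "recovered", "ambiguous", "unmatched"),
                    levels = c("direct", "recovered", "ambiguous", "unmatched")),
    n = c(r$n_direct, r$n_recovered, r$n_ambiguous, r$n_unmatched)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n, fill = .data$status)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "trait rows",
                  title = "Name reconciliation outcome") +
    ggplot2::theme_minimal()
}

#' Read a comparative trait table
#'
#' Header row required; first column is the species name. All columns are
#' read as character so trait fields pass through reconciliation
#' byte-identical.
#'
#' @param path Trait CSV path.
#' @return Tibble of character columns.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path, call. = FALSE)
  out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(out) == 0L) stop("no data rows in trait file: ", path, call. = FALSE)
  out
}

# write a character tibble as CSV with minimal quoting, byte-stable
write_csv_bytes <- function(df, path) {
  header <- paste(csv_quote(names(df)), collapse = ",")
  cols <- lapply(df, function(col) csv_quote(as.character(col)))
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Write reconciliation outputs
#'
#' Emits the rewritten trait CSV (header preserved, matched-name column
#' appended), a machine-readable one-line summary TSV, and optionally the
#' per-name ledger TSV. Re-running on the same inputs is byte-identical.
#'
#' @param result A `reconcile_result`.
#' @param path Output trait CSV path.
#' @param report_path Optional summary TSV path.
#' @param ledger_path Optional per-name ledger TSV path.
#' @param quiet Suppress the printed report?
#' @return `path`, invisibly.
#' @export
write_reconciled <- function(result, path, report_path = NULL,
                             ledger_path = NULL, quiet = FALSE) {
  stopifnot(inherits(result, "reconcile_result"))
  write_csv_bytes(result$table, path)
  if (!is.null(report_path)) {
    g <- glance(result)
    lines <- c(paste(names(g), collapse = "\t"),
               paste(vapply(g, as.character, ""), collapse = "\t"))
    writeLines(lines, report_path, useBytes = TRUE)
  }
  if (!is.null(ledger_path)) {
    l <- result$report$ledger
    l$tip[is.na(l$tip)] <- ""
    lines <- c("original\tkey\tstatus\ttip",
               sprintf("%s\t%s\t%s\t%s", l$original, l$key, l$status, l$tip))
    writeLines(lines, ledger_path, useBytes = TRUE)
  }
  if (!quiet) print(result$report)
  invisible(path)
}
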