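#' Load a local synonym backbone from TSV
#'
#' A backbone is the offline synonym source: a tab-separated, UTF-8 table
#' with header `accepted_name<TAB>synonym<TAB>status`, one row per
#' (accepted, synonym) pair. Accepted names with no synonyms appear once with
#' an empty synonym field; `status` is one of `homotypic`, `heterotypic`,
#' `orthographic`, `unknown`. Duplicate accepted-name rows merge with
#' synonym-set union. A reverse index from the normalized key of every name
#' (accepted or synonym) to its accepted name is built at load time.
#'
#' If one synonym key maps to two different accepted names (a cross-code
#' homonym in the backbone), the collision is surfaced: a warning names both
#' accepted names, the key is registered in the collision set, and
#' [resolve_local()] flags queries hitting it as ambiguous rather than
#' picking one.
#'
#' @param path Path to the backbone TSV.
#' @return A `backbone_table` object.
#' @export
load_backbone <- function(path) {
  if (!file.exists(path)) stop("backbone file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) stop("empty backbone file: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("accepted_name", "synonym"))) {
    stop("backbone header must start 'accepted_name\\tsynonym': ", path,
         call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L | nf > 3L)) {
    bad <- which(nf < 2L | nf > 3L)[1]
    stop(sprintf("backbone format error at line %d of %s: expected 2-3 tab-separated fields, got %d",
                 bad + 1L, path, nf[bad]), call. = FALSE)
  }
  rows <- tibble::tibble(
    accepted = vapply(fields, `[`, "", 1L),
    synonym  = vapply(fields, function(f) if (length(f) >= 2) f[2] else "", ""),
    status   = vapply(fields, function(f) if (length(f) >= 3) f[3] else "unknown", "")
  )
  rows$status[!nzchar(rows$status)] <- "unknown"
  build_backbone(rows)
}

#' Build a backbone table from (accepted, synonym, status) rows
#'
#' Programmatic constructor used by [load_backbone()] and by the synthetic
#' generator. Rows with an empty `synonym` register the accepted name alone.
#'
#' @param rows Tibble/data frame with columns `accepted`, `synonym`,
#'   `status` (status optional, defaults `"unknown"`).
#' @return A `backbone_table`.
#' @export
build_backbone <- function(rows) {
  rows <- tibble::as_tibble(rows)
  if (!"status" %in% names(rows)) rows$status <- "unknown"
  valid_status <- c("homotypic", "heterotypic", "orthographic", "unknown")
  bad <- setdiff(unique(rows$status[nzchar(rows$synonym)]), valid_status)
  if (length(bad)) {
    stop("invalid synonym status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  acc_key <- normalize_key(rows$accepted)
  first <- !duplicated(acc_key)
  accepted_order <- rows$accepted[first]
  groups <- split(seq_len(nrow(rows)), factor(acc_key, levels = acc_key[first]))
  entries <- purrr::map2(accepted_order, groups, function(a, idx) {
    syn <- rows$synonym[idx]
    st <- rows$status[idx]
    keep <- nzchar(syn)
    syn <- syn[keep]; st <- st[keep]
    # drop self-listing and dedupe synonyms under key, first spelling kept
    syn_key <- normalize_key(syn)
    ok <- syn_key != normalize_key(a) & !duplicated(syn_key)
    list(accepted = a, synonyms = syn[ok], status = st[ok])
  })
  names(entries) <- vapply(entries, `[[`, "", "accepted")

  # reverse index: key -> accepted name; collisions surfaced, not resolved
  index <- new.env(parent = emptyenv())
  collisions <- list()
  add_key <- function(key, accepted) {
    prev <- index[[key]]
    if (is.null(prev)) {
      index[[key]] <- accepted
    } else if (!identical(normalize_key(prev), normalize_key(accepted))) {
      collisions[[key]] <<- unique(c(collisions[[key]], prev, accepted))
    }
  }
  for (e in entries) {
    add_key(normalize_key(e$accepted), e$accepted)
    for (s in e$synonyms) add_key(normalize_key(s), e$accepted)
  }
  if (length(collisions)) {
    msg <- vapply(names(collisions), function(k) {
      sprintf("'%s' -> {%s}", k, paste(collisions[[k]], collapse = ", "))
    }, "")
    warning("backbone homonym collision(s), queries hitting these keys will be flagged ambiguous: ",
            paste(msg, collapse = "; "), call. = FALSE)
  }
  structure(
    list(entries = entries, index = index, collisions = collisions),
    class = "backbone_table"
  )
}

#' @export
print.backbone_table <- function(x, ...) {
  n_syn <- sum(vapply(x$entries, function(e) length(e$synonyms), integer(1)))
  cat(sprintf("<backbone_table> %d accepted names, %d synonyms, %d homonym collision key(s)\n",
              length(x$entries), n_syn, length(x$collisions)))
  invisible(x)
}

#' Number of accepted names in a backbone
#' @param table A `backbone_table`.
#' @return Integer count.
#' @export
backbone_size <- function(table) length(table$entries)

#' Backbone as a tidy tibble
#'
#' One row per (accepted, synonym) pair, accepted names without synonyms as a
#' single row with `synonym = ""`. This is the serialization order used by
#' [write_backbone()].
#'
#' @param table A `backbone_table`.
#' @return Tibble with columns `accepted`, `synonym`, `status`.
#' @export
backbone_rows <- function(table) {
  purrr::map_dfr(table$entries, function(e) {
    if (length(e$synonyms) == 0L) {
      tibble::tibble(accepted = e$accepted, synonym = "", status = "")
    } else {
      tibble::tibble(accepted = e$accepted, synonym = e$synonyms, status = e$status)
    }
  })
}

#' Write a backbone table as TSV
#'
#' Inverse of [load_backbone()]: writing and reloading yields a table with
#' identical resolution behavior, and write-read-write is byte-identical.
#'
#' @param table A `backbone_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_backbone <- function(table, path) {
  rows <- backbone_rows(table)
  lines <- c("accepted_name\tsynonym\tstatus",
             sprintf("%s\t%s\t%s", rows$accepted, rows$synonym, rows$status))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Resolve a name against a local backbone
#'
#' Looks the query's normalized key up in the reverse index. A hit on an
#' accepted name or any synonym returns a matched record whose `canonical` is
#' the accepted name and whose `synonyms` are all other names in that entry's
#' cloud (accepted + synonyms, minus the query itself), canonical spelling
#' first. A key in the homonym collision set is flagged ambiguous with all
#' candidate accepted names rather than resolved. Anything else is unmatched.
#'
#' @param table A `backbone_table`.
#' @param query Single name string.
#' @return A one-row `synonym_record` tibble (see [synonym_record()]).
#' @export
resolve_local <- function(table, query) {
  key <- normalize_key(query)
  if (key %in% names(table$collisions)) {
    return(synonym_record(query, matched = FALSE, ambiguous = TRUE,
                          candidates = table$collisions[[key]],
                          source = "local"))
  }
  accepted <- table$index[[key]]
  if (is.null(accepted)) {
    return(synonym_record(query, matched = FALSE, source = "local"))
  }
  e <- table$entries[[accepted]]
  cloud <- c(e$accepted, e$synonyms)
  cloud <- cloud[normalize_key(cloud) != key]
  synonym_record(query, matched = TRUE, canonical = e$accepted,
                 current = e$accepted, synonyms = cloud, source = "local")
}
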