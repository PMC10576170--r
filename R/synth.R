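#' Configuration for the synthetic taxonomy generator
#'
#' The generator plants known nomenclature drift — synonym clouds with
#' truthful class labels, a reference tree over accepted names, and a trait
#' table whose labels mix accepted names, planted synonyms and orphans — so
#' the whole resolve-and-reconcile pipeline can be checked against ground
#' truth offline.
#'
#' @param n_species Number of accepted species.
#' @param synonym_rate Mean synonyms per accepted name (Poisson draw per
#'   species).
#' @param p_genus_transfer Probability a synonym moves to a different genus
#'   (heterotypic-style drift).
#' @param p_suffix_swap Probability a synonym is an orthographic variant via
#'   a substitution rule ending swap.
#' @param p_trait_synonym Fraction of trait rows labeled with a planted
#'   synonym instead of the accepted name.
#' @param p_trait_orphan Fraction of trait rows labeled with a name absent
#'   from the backbone.
#' @param plant_homonyms Plant one shared name into two species' clouds, to
#'   exercise the ambiguity path deliberately (default off).
#' @param seed RNG seed; identical configs give identical output.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_species = 100, synonym_rate = 1.5,
                         p_genus_transfer = 0.3, p_suffix_swap = 0.4,
                         p_trait_synonym = 0.2, p_trait_orphan = 0.05,
                         plant_homonyms = FALSE, seed = 1L) {
  probs <- c(p_genus_transfer = p_genus_transfer, p_suffix_swap = p_suffix_swap,
             p_trait_synonym = p_trait_synonym, p_trait_orphan = p_trait_orphan)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_trait_synonym + p_trait_orphan > 1) {
    stop("p_trait_synonym + p_trait_orphan must not exceed 1", call. = FALSE)
  }
  if (!is.numeric(n_species) || n_species < 1) {
    stop("n_species must be a positive count", call. = FALSE)
  }
  if (synonym_rate < 0) stop("synonym_rate must be non-negative", call. = FALSE)
  structure(list(
    n_species = as.integer(n_species), synonym_rate = synonym_rate,
    p_genus_transfer = p_genus_transfer, p_suffix_swap = p_suffix_swap,
    p_trait_synonym = p_trait_synonym, p_trait_orphan = p_trait_orphan,
    plant_homonyms = isTRUE(plant_homonyms), seed = as.integer(seed)
  ), class = "synth_config")
}

# pronounceable pseudo-Latin stems from a fixed syllable inventory
.syllables <- c("ba", "ca", "da", "fe", "ga", "hi", "ko", "la", "me", "ni",
                "or", "pa", "qui", "ra", "sa", "te", "ul", "ve", "xa", "zo",
                "bra", "cli", "dro", "fla", "gru", "pleu", "stra", "tri")
.epithet_endings <- c("us", "a", "um", "is", "ii", "ae")

rand_stem <- function(n_syll) {
  paste(sample(.syllables, n_syll, replace = TRUE), collapse = "")
}

rand_genus <- function() {
  stem <- rand_stem(sample(2:3, 1))
  paste0(toupper(substr(stem, 1, 1)), substr(stem, 2, nchar(stem)),
         sample(c("us", "a", "ia", "odon", "ix"), 1))
}

rand_epithet <- function() {
  paste0(rand_stem(sample(2:3, 1)), sample(.epithet_endings, 1))
}

#' Generate a synthetic taxonomy with planted synonym clouds
#'
#' Draws `n_species` pseudo-Latin binomials (capitalized genus, epithet with
#' a Latin ending so the substitution rules apply), then per species a
#' Poisson(`synonym_rate`) number of synonyms, each built by genus transfer
#' and/or an epithet suffix swap according to the configured probabilities; a
#' synonym where neither fires keeps the genus and gets a fresh epithet.
#' Status flags are truthful: suffix-swap-only synonyms are `orthographic`,
#' genus transfers `heterotypic`, fresh-epithet renames `homotypic`. All
#' generated names are unique under [normalize_key()] unless homonym planting
#' is on.
#'
#' @param config A [synth_config()].
#' @return List with `$backbone` (a `backbone_table`) and `$truth` (the
#'   ground-truth tibble: `name`, `accepted`, `class`, underscore-separated).
#' @export
generate_taxonomy <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  used <- new.env(parent = emptyenv())
  claim <- function(name) {
    key <- normalize_key(name)
    if (!is.null(used[[key]])) return(FALSE)
    used[[key]] <- TRUE
    TRUE
  }
  fresh_binomial <- function() {
    repeat {
      nm <- paste(rand_genus(), rand_epithet(), sep = "_")
      if (claim(nm)) return(nm)
    }
  }
  accepted <- character(config$n_species)
  for (i in seq_len(config$n_species)) accepted[i] <- fresh_binomial()
  genera <- vapply(strsplit(accepted, "_", fixed = TRUE), `[`, "", 1L)
  rules <- default_substitution_rules()

  rows <- vector("list", config$n_species)
  truth <- vector("list", config$n_species)
  for (i in seq_len(config$n_species)) {
    acc <- accepted[i]
    parts <- strsplit(acc, "_", fixed = TRUE)[[1]]
    n_syn <- stats::rpois(1, config$synonym_rate)
    syn <- character(0)
    status <- character(0)
    guard <- 0L
    while (length(syn) < n_syn && guard < n_syn * 20L + 20L) {
      guard <- guard + 1L
      transfer <- stats::runif(1) < config$p_genus_transfer
      swap <- stats::runif(1) < config$p_suffix_swap
      genus <- if (transfer) {
        pool <- setdiff(unique(genera), parts[1])
        if (length(pool)) sample(pool, 1) else rand_genus()
      } else {
        parts[1]
      }
      epithet <- parts[2]
      if (swap) {
        variants <- generate_variants(
          tibble::tibble(genus = parts[1], epithet = epithet), rules)
        if (nrow(variants)) epithet <- sample(variants$epithet, 1)
      }
      if (!transfer && !swap) epithet <- rand_epithet()
      cand <- paste(genus, epithet, sep = "_")
      if (!claim(cand)) next
      syn <- c(syn, cand)
      status <- c(status,
                  if (transfer) "heterotypic"
                  else if (swap) "orthographic"
                  else "homotypic")
    }
    rows[[i]] <- tibble::tibble(
      accepted = acc,
      synonym = if (length(syn)) syn else "",
      status = if (length(syn)) status else ""
    )
    truth[[i]] <- tibble::tibble(
      name = c(acc, syn), accepted = acc, class = c("accepted", status)
    )
  }
  backbone_df <- dplyr::bind_rows(rows)
  truth_df <- dplyr::bind_rows(truth)

  if (config$plant_homonyms && config$n_species >= 2L) {
    # one shared name in two species' clouds: a deliberate homonym
    shared <- fresh_binomial()
    extra <- tibble::tibble(accepted = accepted[1:2], synonym = shared,
                            status = "unknown")
    backbone_df <- dplyr::bind_rows(backbone_df, extra)
    truth_df <- dplyr::bind_rows(
      truth_df,
      tibble::tibble(name = shared, accepted = accepted[1:2], class = "homonym"))
  }
  backbone <- suppressWarnings(build_backbone(backbone_df))
  list(backbone = backbone, truth = truth_df)
}

#' Random reference tree over the accepted names
#'
#' A random binary tree (sequential random splits) whose leaf set is exactly
#' the accepted names, underscore-separated, with uniform(0, 1] branch
#' lengths. The tree is a label carrier for reconciliation tests, not a
#' model of evolutionary history.
#'
#' @param truth Ground-truth tibble from [generate_taxonomy()].
#' @param seed RNG seed for the topology and branch lengths.
#' @return An `ape::phylo` object.
#' @export
make_tree <- function(truth, seed = 1L) {
  accepted <- unique(truth$accepted)
  stopifnot(length(accepted) >= 2L)
  set.seed(seed)
  ape::rtree(length(accepted), tip.label = accepted,
             br = function(n) stats::runif(n, min = .Machine$double.eps, max = 1))
}

#' Synthetic trait table with planted label drift
#'
#' One row per accepted species, in accepted order. Each row's name column is
#' the accepted name, a uniformly chosen planted synonym (probability
#' `p_trait_synonym`; falls back to the accepted name when the species has no
#' synonyms), or a fresh orphan name absent from the backbone (probability
#' `p_trait_orphan`); one standard-normal trait column. The expected
#' reconciliation report is computed by bookkeeping at planting time — an
#' independent path from the reconciler, so end-to-end tests compare two
#' different computations of the same counts.
#'
#' @param truth Ground-truth tibble from [generate_taxonomy()].
#' @param config The same [synth_config()] used for generation.
#' @return List: `$traits` (tibble `species`, `trait`), `$expected` (tibble
#'   `n_input`, `n_direct`, `n_recovered`, `n_ambiguous`, `n_unmatched`),
#'   `$labels` (tibble `species`, `label_class`).
#' @export
make_trait_table <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  accepted <- unique(truth$accepted)
  syn_by_acc <- split(truth$name[truth$class != "accepted"],
                      factor(truth$accepted[truth$class != "accepted"],
                             levels = accepted))
  ambiguous_names <- if ("homonym" %in% truth$class) {
    unique(truth$name[truth$class == "homonym"])
  } else {
    character(0)
  }
  used_keys <- unique(normalize_key(truth$name))
  n <- length(accepted)
  draw <- stats::runif(n)
  label <- character(n)
  class <- character(n)
  for (i in seq_len(n)) {
    syns <- syn_by_acc[[i]]
    if (draw[i] < config$p_trait_synonym) {
      # a species with no planted synonyms keeps its accepted label (direct)
      if (length(syns)) {
        pick <- if (length(syns) == 1L) syns else sample(syns, 1)
        label[i] <- pick
        class[i] <- if (pick %in% ambiguous_names) "ambiguous" else "recovered"
      } else {
        label[i] <- accepted[i]
        class[i] <- "direct"
      }
    } else if (draw[i] < config$p_trait_synonym + config$p_trait_orphan) {
      repeat {
        orphan <- paste(rand_genus(), rand_epithet(), sep = "_")
        if (!normalize_key(orphan) %in% used_keys) break
      }
      used_keys <- c(used_keys, normalize_key(orphan))
      label[i] <- orphan
      class[i] <- "unmatched"
    } else {
      label[i] <- accepted[i]
      class[i] <- "direct"
    }
  }
  traits <- tibble::tibble(species = label,
                           trait = stats::rnorm(n))
  expected <- tibble::tibble(
    n_input = n,
    n_direct = sum(class == "direct"),
    n_recovered = sum(class == "recovered"),
    n_ambiguous = sum(class == "ambiguous"),
    n_unmatched = sum(class == "unmatched")
  )
  list(traits = traits,
       expected = expected,
       labels = tibble::tibble(species = label, label_class = class))
}

#' Generate and write the full synthetic fixture set
#'
#' Convenience wrapper: backbone TSV, Newick tree, trait CSV, ground-truth
#' TSV, and a JSON sidecar echoing the configuration for reproducibility.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"synth"`.
#' @return Named list of the written paths, invisibly; the generated objects
#'   as attributes `backbone`, `truth`, `tree`, `traits`, `expected`.
#' @export
write_synth_fixtures <- function(config, dir, prefix = "synth") {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tax <- generate_taxonomy(config)
  tree <- make_tree(tax$truth, seed = config$seed)
  tt <- make_trait_table(tax$truth, config)
  paths <- list(
    backbone = file.path(dir, paste0(prefix, "_backbone.tsv")),
    tree = file.path(dir, paste0(prefix, "_tree.nwk")),
    traits = file.path(dir, paste0(prefix, "_traits.csv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")),
    config = file.path(dir, paste0(prefix, "_config.json"))
  )
  write_backbone(tax$backbone, paths$backbone)
  ape::write.tree(tree, file = paths$tree)
  # trait values written with full precision, locale-independent
  traits_chr <- tibble::tibble(
    species = tt$traits$species,
    trait = sprintf("%.15g", tt$traits$trait)
  )
  write_csv_bytes(traits_chr, paths$traits)
  truth_lines <- c("name\taccepted\tclass",
                   sprintf("%s\t%s\t%s", tax$truth$name, tax$truth$accepted,
                           tax$truth$class))
  writeLines(truth_lines, paths$truth, useBytes = TRUE)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       pretty = TRUE)
  out <- paths
  attr(out, "backbone") <- tax$backbone
  attr(out, "truth") <- tax$truth
  attr(out, "tree") <- tree
  attr(out, "traits") <- tt$traits
  attr(out, "expected") <- tt$expected
  invisible(out)
}
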