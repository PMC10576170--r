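test_that("backbone TSV loads with a complete reverse index", {
  path <- write_backbone_tsv(list(
    c("Panthera leo", "Felis leo", "heterotypic"),
    c("Panthera leo", "Leo leo", "homotypic"),
    c("Ursus arctos", "Ursus arctus", "orthographic"),
    c("Vulpes vulpes", "", "")
  ))
  bb <- load_backbone(path)
  expect_equal(backbone_size(bb), 3L)
  # reverse index covers accepted + distinct synonyms
  expect_equal(length(ls(bb$index)), 3L + 3L)
  expect_equal(bb$index[[normalize_key("Felis_leo")]], "Panthera leo")
})

test_that("header-only backbone yields an empty table where every lookup is unmatched", {
  path <- write_backbone_tsv(list())
  bb <- load_backbone(path)
  expect_equal(backbone_size(bb), 0L)
  expect_false(resolve_local(bb, "Panthera_leo")$matched)
})

test_that("wrong column counts are reported with their line number", {
  path <- tempfile()
  writeLines(c("accepted_name\tsynonym\tstatus", "A b\tA c\tunknown\textra\tmore"),
             path)
  expect_error(load_backbone(path), "line 2")
  expect_error(load_backbone(tempfile()), "not found")
})

test_that("archaic names resolve to their accepted replacement", {
  bb <- load_backbone(lion_backbone())
  rec <- resolve_local(bb, "Felis_leo")
  expect_true(rec$matched)
  expect_equal(rec$canonical, "Panthera leo")
  expect_true("Panthera leo" %in% rec$synonyms[[1]])
  # self-lookup of the accepted name returns its synonym list
  rec2 <- resolve_local(bb, "Panthera_leo")
  expect_true(rec2$matched)
  expect_equal(rec2$canonical, "Panthera leo")
  expect_equal(rec2$synonyms[[1]], "Felis leo")
  # absent key
  expect_false(resolve_local(bb, "Nonexistens specius")$matched)
})

test_that("a record never lists the query's own key among its synonyms", {
  cfg <- synth_config(n_species = 80, synonym_rate = 2, seed = 3)
  tax <- generate_taxonomy(cfg)
  src <- local_source(tax$backbone)
  for (nm in sample(tax$truth$name, 40)) {
    rec <- resolve_with_fallback(src, nm)
    expect_false(normalize_key(nm) %in% normalize_key(rec$synonyms[[1]]))
    expect_false(any(duplicated(normalize_key(rec$synonyms[[1]]))))
  }
})

test_that("homonym collisions are surfaced, never silently resolved", {
  path <- write_backbone_tsv(list(
    c("Aus bus", "Xus shared", "unknown"),
    c("Cus dus", "Xus shared", "unknown")
  ))
  expect_warning(bb <- load_backbone(path), "collision")
  rec <- resolve_local(bb, "Xus_shared")
  expect_false(rec$matched)
  expect_true(rec$ambiguous)
  expect_setequal(rec$candidates[[1]], c("Aus bus", "Cus dus"))
})

test_that("reverse-index resolution equals a brute-force scan over all entries", {
  cfg <- synth_config(n_species = 40, synonym_rate = 2, seed = 9)
  tax <- generate_taxonomy(cfg)
  bb <- tax$backbone
  rows <- backbone_rows(bb)
  queries <- c(tax$truth$name, "Absentis nomen")
  for (q in queries) {
    qkey <- normalize_key(q)
    # oracle: scan every entry's full cloud for the key
    hit <- character(0)
    for (acc in unique(rows$accepted)) {
      cloud <- c(acc, rows$synonym[rows$accepted == acc])
      cloud <- cloud[nzchar(cloud)]
      if (qkey %in% normalize_key(cloud)) hit <- c(hit, acc)
    }
    rec <- resolve_local(bb, q)
    if (length(hit) == 1L) {
      expect_true(rec$matched)
      expect_equal(rec$canonical, hit)
    } else if (length(hit) == 0L) {
      expect_false(rec$matched)
    }
  }
})

test_that("fallback resolves suffix variants and reports the variant used", {
  bb <- build_backbone(tibble::tibble(accepted = "Orthriophis taeniurus",
                                      synonym = "", status = ""))
  src <- local_source(bb)
  rec <- resolve_with_fallback(src, "Orthriophis taeniurum")
  expect_true(rec$matched)
  expect_equal(rec$via_variant, "Orthriophis taeniurus")
  expect_equal(rec$canonical, "Orthriophis taeniurus")
  # verbatim matches never set via_variant
  rec2 <- resolve_with_fallback(src, "Orthriophis taeniurus")
  expect_true(rec2$matched)
  expect_true(is.na(rec2$via_variant))
  # empty rule set disables the fallback entirely
  rec3 <- resolve_with_fallback(src, "Orthriophis taeniurum",
                                rules = no_substitution_rules())
  expect_false(rec3$matched)
})

test_that("fallback with empty rules equals plain resolution on many queries", {
  cfg <- synth_config(n_species = 50, synonym_rate = 1, seed = 21)
  tax <- generate_taxonomy(cfg)
  src <- local_source(tax$backbone)
  queries <- c(sample(tax$truth$name, 20), "Absentis nomen", "Aliud_ignotum")
  for (q in queries) {
    a <- resolve_with_fallback(src, q, rules = no_substitution_rules())
    b <- resolve_local(tax$backbone, q)
    expect_equal(a$matched, b$matched)
    expect_equal(a$canonical, b$canonical)
    expect_equal(a$synonyms[[1]], b$synonyms[[1]])
  }
})

test_that("via_variant is always a member of the query's variant set", {
  cfg <- synth_config(n_species = 60, synonym_rate = 1.5, p_suffix_swap = 0.8,
                      seed = 13)
  tax <- generate_taxonomy(cfg)
  src <- local_source(tax$backbone)
  # probe with suffix-mutated versions of accepted names
  for (nm in sample(unique(tax$truth$accepted), 30)) {
    vars <- generate_variants(nm)
    if (nrow(vars) == 0) next
    probe <- vars$raw[1]
    rec <- resolve_with_fallback(src, probe)
    if (!is.na(rec$via_variant)) {
      allowed <- format_taxon(generate_variants(probe), separator = "_")
      expect_true(rec$via_variant %in% allowed)
    }
  }
})

test_that("identifier lists dedupe keeping first occurrence in order", {
  expect_equal(dedupe_identifiers(c(7, 3, 7, 7, 1)), c(7, 3, 1))
  expect_equal(dedupe_identifiers(integer()), integer())
  set.seed(4)
  for (i in 1:20) {
    ids <- sample(1:10, 30, replace = TRUE)
    out <- dedupe_identifiers(ids)
    expect_setequal(out, unique(ids))
    expect_equal(length(out), length(unique(ids)))
    expect_false(any(duplicated(out)))
  }
})

test_that("name harvesting searches nested fields exhaustively and dedupes", {
  entry <- list(Name = "A b", OtherNames = list(synonym = c("A c", "A c")))
  expect_equal(harvest_names(entry), c("A b", "A c"))
  expect_equal(harvest_names(list(TaxId = "1", Rank = "species")), character())
  expect_equal(harvest_names(list()), character())
})

test_that("a recorded NCBI-style record fixture harvests its known name list", {
  path <- system.file("extdata", "ncbi_taxon_record_synthetic.json",
                      package = "synotip")
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  found <- harvest_names(rec$record)
  expect_equal(found, c("Panthera leo", "lion", "Felis leo",
                        "Panthera leo (Linnaeus, 1758)",
                        "Felis leo Linnaeus, 1758"))
})

test_that("replay sources resolve recorded responses and miss cleanly", {
  dir <- tempfile(); dir.create(dir)
  jsonlite::write_json(
    list(matched = TRUE, canonical = "Panthera leo",
         synonyms = c("Panthera leo", "Felis leo")),
    file.path(dir, "felis_leo.json"), auto_unbox = TRUE)
  file.copy(system.file("extdata", "ncbi_taxon_record_synthetic.json",
                        package = "synotip"),
            file.path(dir, "panthera_leo.json"))
  src <- replay_source(dir, name = "gbif")
  rec <- src$resolve("Felis_leo")
  expect_true(rec$matched)
  expect_equal(rec$canonical, "Panthera leo")
  expect_equal(rec$source, "gbif")
  # raw-record fixture goes through harvesting; own key excluded
  rec2 <- src$resolve("Panthera_leo")
  expect_true(rec2$matched)
  expect_true("Felis leo" %in% rec2$synonyms[[1]])
  expect_false("panthera leo" %in% normalize_key(rec2$synonyms[[1]]))
  # no fixture file = unmatched, not an error
  expect_false(src$resolve("Absentis nomen")$matched)
})

test_that("backbone serialization round-trips resolution behavior", {
  cfg <- synth_config(n_species = 30, synonym_rate = 2, seed = 17)
  tax <- generate_taxonomy(cfg)
  p1 <- tempfile(); p2 <- tempfile()
  write_backbone(tax$backbone, p1)
  bb2 <- load_backbone(p1)
  write_backbone(bb2, p2)
  expect_identical(readLines(p1), readLines(p2))
  for (q in sample(tax$truth$name, 25)) {
    a <- resolve_local(tax$backbone, q)
    b <- resolve_local(bb2, q)
    expect_equal(a$matched, b$matched)
    expect_equal(a$canonical, b$canonical)
    expect_equal(sort(a$synonyms[[1]]), sort(b$synonyms[[1]]))
  }
})
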