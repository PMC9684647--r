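test_that("packaged ontologies load with the published unit inventories", {
  h <- get_fixture("ont_h")
  m <- get_fixture("ont_m")
  expect_equal(nrow(h$units), 73L)
  expect_equal(nrow(m$units), 40L)

  ch <- count_units(h, "lobe")
  expect_equal(setNames(ch$n, ch$lobe),
               c(frontal = 27L, insular = 2L, occipital = 9L, paralimbic = 7L,
                 parietal = 13L, temporal = 15L))
  cm <- count_units(m, "lobe")
  expect_equal(setNames(cm$n, cm$lobe),
               c(frontal = 16L, insular = 1L, occipital = 7L, paralimbic = 4L,
                 parietal = 7L, temporal = 5L))
  expect_equal(sum(ch$n), count_units(h)$n)
  expect_equal(sum(cm$n), count_units(m)$n)
  expect_error(count_units(h, "banana"), class = "hoa_usage_error")
})

test_that("unit families match the revision scheme", {
  h <- get_fixture("ont_h")
  m <- get_fixture("ont_m")
  # macaque orbital family subdivided into five units
  expect_length(intersect(c("FOCa", "FOCL", "FOCm", "FOCp", "FMC"), m$units$id), 5L)
  # human inferior frontal gyrus expanded to four units
  expect_length(intersect(c("F3a", "F3o", "F3orb", "F3t"), h$units$id), 4L)
  # human fronto-orbital cortex subdivided into four units
  expect_length(intersect(c("FOCa", "FOCL", "FOCm", "FOCp"), h$units$id), 4L)
})

test_that("validation reports closure for packaged data and flags defects", {
  for (sp in c("ont_h", "ont_m")) {
    rep <- validate_ontology(get_fixture(sp))
    expect_length(rep$unresolved, 0L)
    expect_length(rep$duplicate_ids, 0L)
    expect_length(rep$incomplete_slots, 0L)
    expect_length(rep$merge_problems, 0L)
    expect_length(rep$equivalence_problems, 0L)
  }
  # injected dangling border reference
  bad <- get_fixture("ont_h")
  bad$borders$target[bad$borders$pu == "AGa" & bad$borders$target == "ip"] <- "xyz"
  rep <- validate_ontology(bad)
  expect_true(any(grepl("xyz", rep$unresolved)))
  # injected duplicate id
  dup <- get_fixture("ont_h")
  dup$units$id[2] <- "AGa"
  expect_true("AGa" %in% validate_ontology(dup)$duplicate_ids)
})

test_that("derived-line symbols used by the rules are each defined once", {
  for (sp in c("ont_h", "ont_m")) {
    ont <- get_fixture(sp)
    used <- unique(ont$borders$target[ont$borders$kind == "derived-line" &
                                        !is.na(ont$borders$target)])
    expect_true(all(used %in% ont$derived_lines$id))
    expect_false(anyDuplicated(ont$derived_lines$id) > 0)
  }
})

test_that("unit lookup returns the printed border slots", {
  h <- get_fixture("ont_h")
  fo <- get_unit(h, "FO")
  expect_identical(fo$borders$anterior, "n/a")
  expect_setequal(get_unit(h, "AGa")$borders$anterior$target, c("CP E", "im"))
  m <- get_fixture("ont_m")
  tp <- get_unit(m, "TP")
  expect_equal(tp$borders$posterior$target, "CP E")
  expect_true(all(c(tp$borders$anterior$target,
                    tp$borders$medial_inferior$target,
                    tp$borders$lateral_superior$target) == "HM"))
  expect_error(get_unit(h, "nope"), class = "hoa_lookup_error")
})

test_that("sulcus records carry nomenclature ids or the explicit marker", {
  h <- get_fixture("ont_h")
  for (col in c("neuronames_id", "tna2_id", "fipat_id")) {
    expect_true(all(grepl("^[0-9]+$", h$sulci[[col]]) | h$sulci[[col]] == "n.d."))
  }
  expect_true(h$sulci$may_duplicate[h$sulci$abbrev == "lorb"])
  expect_true(all(h$sulci$provisional[h$sulci$abbrev %in% c("ma", "par", "phr")]))
})

test_that("ontology serializes to JSON and back unchanged", {
  h <- get_fixture("ont_h")
  path <- withr::local_tempfile(fileext = ".json")
  ontology_to_json(h, path)
  h2 <- ontology_from_json(path)
  expect_equal(h2$species, h$species)
  expect_equal(as.data.frame(h2$units), as.data.frame(h$units))
  expect_equal(as.data.frame(h2$borders), as.data.frame(h$borders))
  expect_equal(as.data.frame(h2$sulci), as.data.frame(h$sulci))
})

test_that("degenerate ontology sources raise parse errors", {
  dir <- withr::local_tempdir()
  file.create(file.path(dir, "human_units.tsv"))
  expect_error(load_ontology("human", source_path = dir), class = "hoa_parse_error")
  expect_error(load_ontology("human", source_path = withr::local_tempdir()),
               class = "hoa_input_error")
})
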