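test_that("human-to-macaque homologs are unique and match the table", {
  h <- get_fixture("ont_h")
  expect_equal(homolog(h, "SMA", "human_to_macaque")$mhoa_pu[[1]], "PRGm/SMA")
  expect_equal(homolog(h, "CALCi", "human_to_macaque")$mhoa_pu[[1]], "CALCi")
  # a human unit may map onto more than one macaque unit within its row
  expect_setequal(homolog(h, "PRGLi", "human_to_macaque")$mhoa_pu[[1]],
                  c("PRGL", "PMv"))
  # every human unit has exactly one equivalence row
  for (id in h$units$id) {
    expect_equal(nrow(homolog(h, id, "human_to_macaque")), 1L, info = id)
  }
})

test_that("macaque-to-human homology is one-to-many", {
  m <- get_fixture("ont_m")
  back <- homolog(m, "ITG", "macaque_to_human")
  expect_setequal(back$hhoa_pu,
                  c("T2a", "T2p", "T3a", "T3p", "TFa", "TFp", "TO2", "TO3"))
  expect_warning(homolog(m, "NOPE", "macaque_to_human"))
})

test_that("Brodmann queries reproduce an independent scan of the table", {
  h <- get_fixture("ont_h")
  # independent oracle: scan the raw transcription with plain string ops,
  # bypassing the package's cell parser
  raw <- read.delim(system.file("extdata", "ontology", "equivalences.tsv",
                                package = "hoacompare"), stringsAsFactors = FALSE)
  strip_minor <- function(s) gsub("\\([^)]*\\)", "", s)
  major_has <- function(cell, area) {
    toks <- trimws(unlist(strsplit(strip_minor(cell), ",")))
    toks <- trimws(gsub("\\*+$", "", toks))
    toks <- unlist(lapply(strsplit(toks, " "), function(t) t[1]))
    area %in% toks
  }
  expected17 <- sort(raw$hhoa_pu[vapply(raw$human_ba, major_has, logical(1),
                                        area = "17")])
  expect_equal(brodmann_to_units(h, "17", "human"), expected17)
  expect_equal(expected17, c("CALCi", "CALCs", "OP", "SCALC"))

  expected6 <- sort(raw$hhoa_pu[vapply(raw$human_ba, major_has, logical(1),
                                       area = "6")])
  expect_equal(brodmann_to_units(h, "6", "human"), expected6)
})

test_that("minor designations and footnote distinctions are honored", {
  h <- get_fixture("ont_h")
  # area 17 appears as a minor (parenthesized) designation for LG only
  expect_false("LG" %in% brodmann_to_units(h, "17", "human"))
  expect_true("LG" %in% brodmann_to_units(h, "17", "human", include_minor = TRUE))
  # unknown area gives an empty result, not an error
  expect_length(brodmann_to_units(h, "99", "human"), 0L)
  # monkey area 13 is insular cortex; the Walker-13 orbitofrontal row must
  # not be returned by a Brodmann query
  hits <- brodmann_to_units(h, "13-insular", "macaque", include_minor = TRUE)
  expect_equal(hits, "INS")
  expect_false("FOCp" %in% hits)
})

test_that("Walker areas stay outside the non-frontal blocks", {
  h <- get_fixture("ont_h")
  eq <- h$equivalences
  outside <- eq[eq$lobe_group != "frontal", ]
  expect_true(all(vapply(outside$walker, nrow, integer(1)) == 0L))
})
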