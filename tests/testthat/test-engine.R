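test_that("realized borders cover every distinct symbol of the ruleset", {
  ont <- get_fixture("ont_m")
  hemi <- get_fixture("ph_m")$hemisphere
  borders <- realize_borders(ont, hemi)
  symbols <- unique(ont$borders$target[!is.na(ont$borders$target)])
  qualified <- ont$borders |>
    dplyr::filter(!is.na(.data$qualifier)) |>
    dplyr::mutate(key = paste0(.data$target, " (", .data$qualifier, ")"))
  expect_true(all(symbols %in% names(borders)))
  expect_true(all(unique(qualified$key) %in% names(borders)))
  expect_true(all(c("Pl a", "Pl b", "Pl c") %in% names(borders)))
})

test_that("a missing required trace is reported by name", {
  hemi <- get_fixture("ph_m")$hemisphere
  hemi$traces <- hemi$traces |> dplyr::filter(.data$sulcus != "ce")
  expect_error(check_annotation(get_fixture("ont_m"), hemi),
               regexp = "\\bce\\b", class = "hoa_completeness_error")
})

test_that("engine output partitions the ribbon on both species", {
  for (sp in c("h", "m")) {
    lm <- get_fixture(paste0("lm_", sp))
    ph <- get_fixture(paste0("ph_", sp))
    rep <- check_partition(lm, ph$hemisphere)
    expect_equal(rep$coverage, 1)
    expect_equal(rep$overlap_count, 0L)
    expect_length(rep$unlabeled, 0L)
    expect_length(lm$empty_units, 0L)
  }
})

test_that("engine labels match analytic ground truth away from borders", {
  for (sp in c("h", "m")) {
    agree <- interior_agreement(get_fixture(paste0("lm_", sp)),
                                get_fixture(paste0("ph_", sp)))
    expect_gt(agree$n_interior, 5000)
    expect_equal(agree$fraction, 1, info = sp)
  }
})

test_that("labeling is deterministic", {
  lm1 <- get_fixture("lm_m")
  lm2 <- assign_labels(get_fixture("ont_m"), get_fixture("ph_m")$hemisphere)
  expect_identical(lm1$labels, lm2$labels)
  expect_identical(lm1$lut, lm2$lut)
})

test_that("the lateral-orbital merge fires iff the sulcus is single", {
  ont <- get_fixture("ont_h")
  eff1 <- apply_focl_f3o_merge(ont, get_fixture("ph_h_merged")$hemisphere)
  expect_true("FOCL/F3o" %in% eff1$units$id)
  expect_equal(nrow(eff1$units), 72L)
  eff2 <- apply_focl_f3o_merge(ont, get_fixture("ph_h")$hemisphere)
  expect_identical(eff2$units$id, ont$units$id)
  # merge partners are symmetric in the source ontology
  expect_equal(ont$units$merge_partner[ont$units$id == "FOCL"], "F3o")
  expect_equal(ont$units$merge_partner[ont$units$id == "F3o"], "FOCL")
  # macaque input is a no-op
  ontm <- get_fixture("ont_m")
  expect_identical(apply_focl_f3o_merge(ontm, get_fixture("ph_m")$hemisphere), ontm)
  # merged label map has the combined unit and full coverage
  lmm <- get_fixture("lm_h_merged")
  expect_true("FOCL/F3o" %in% lmm$lut$pu)
  agree <- interior_agreement(lmm, get_fixture("ph_h_merged"))
  expect_equal(agree$fraction, 1)
})

test_that("merging changes no voxel outside the union of the two regions", {
  full <- get_fixture("ph_h")
  lm_full <- get_fixture("lm_h")
  lm_merged <- get_fixture("lm_h_merged")
  code <- setNames(lm_full$lut$code, lm_full$lut$pu)
  union_region <- lm_full$labels %in% code[c("FOCL", "F3o")] |
    get_fixture("ph_h_merged")$truth$labels ==
      which(lm_merged$lut$pu == "FOCL/F3o")
  outside <- !union_region & full$hemisphere$ribbon > 0L
  pu_full <- lm_full$lut$pu[lm_full$labels[outside]]
  pu_merged <- lm_merged$lut$pu[lm_merged$labels[outside]]
  expect_equal(mean(pu_full == pu_merged), 1)
})

test_that("mirror-image phantoms yield mirror-image label maps", {
  for (sp in c("h", "m")) {
    r <- get_fixture(paste0("lm_", sp))
    l <- get_fixture(paste0("lm_", sp, "_left"))
    dmx <- dim(r$labels)[1]
    expect_identical(r$labels[dmx:1, , ], l$labels)
  }
})

test_that("jittered annotations disagree only within the border band", {
  ph <- get_fixture("ph_m")
  hemi_j <- perturb_phantom(ph$hemisphere, 0.4, seed = 11)
  lm_j <- assign_labels(get_fixture("ont_m"), hemi_j)
  agree <- interior_agreement(lm_j, ph)
  expect_equal(agree$fraction, 1)
})

test_that("degenerate calcarine banks leave the bank units empty, flagged", {
  lm <- get_fixture("lm_h_nocalc")
  expect_setequal(lm$empty_units, c("CALCi", "CALCs"))
  rep <- check_partition(lm, get_fixture("ph_h_nocalc")$hemisphere)
  expect_equal(rep$coverage, 1)
  agree <- interior_agreement(lm, get_fixture("ph_h_nocalc"))
  expect_equal(agree$fraction, 1)
})

test_that("partition checker flags hand-made gaps", {
  lm <- get_fixture("lm_m")
  hemi <- get_fixture("ph_m")$hemisphere
  broken <- lm
  vox <- which(broken$labels > 0L)[1:10]
  broken$labels[vox] <- 0L
  rep <- check_partition(broken, hemi)
  expect_lt(rep$coverage, 1)
  expect_equal(length(rep$unlabeled), 10L)
})
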