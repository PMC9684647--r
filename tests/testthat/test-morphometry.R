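test_that("volumes are voxel counts times voxel volume", {
  # 1000 voxels of 1 mm3 -> 1.00 cm3
  frame <- hemisphere_frame(c(20, 20, 20))
  lab <- array(0L, c(20, 20, 20))
  lab[1:10, 1:10, 1:10] <- 1L
  lut <- tibble::tibble(code = 1L, pu = "AGa", name = "Angular gyrus, anterior",
                        lobe = "parietal", side = "right")
  lm <- hoacompare:::new_labelmap(frame, lab, lut, "human")
  vol <- compute_volumes(lm)
  expect_equal(vol$voxels, 1000L)
  expect_equal(vol$volume_cm3, 1.00)
})

test_that("per-unit volumes on the phantom equal ground-truth voxel counts", {
  ph <- get_fixture("ph_m")
  vol <- compute_volumes(get_fixture("lm_m"))
  # conservation: per-hemisphere total equals ribbon volume exactly
  expect_identical(sum(vol$voxels), sum(ph$hemisphere$ribbon > 0L))
  # counts agree with direct tabulation of the engine map
  lm <- get_fixture("lm_m")
  direct <- tabulate(lm$labels[lm$labels > 0L], nbins = nrow(lm$lut))
  expect_identical(vol$voxels, direct)
  # empty units keep a zero row
  lmn <- get_fixture("lm_h_nocalc")
  voln <- compute_volumes(lmn)
  expect_true(all(c("CALCi", "CALCs") %in% voln$pu[voln$voxels == 0L]))
  expect_equal(nrow(voln), 73L)
})

test_that("aggregation preserves totals and lobar structure", {
  vol <- compute_volumes(get_fixture("lm_h"))
  by_lobe <- aggregate_volumes(vol, "lobe")
  expect_equal(nrow(by_lobe), 6L)
  expect_identical(sum(by_lobe$voxels), sum(vol$voxels))
  tot <- aggregate_volumes(vol, "total")
  expect_identical(tot$voxels, sum(vol$voxels))
  expect_error(aggregate_volumes(vol, "gyrus"), class = "hoa_usage_error")
})

test_that("volumes scale with the cube of the voxel size", {
  lm <- get_fixture("lm_m")
  v1 <- compute_volumes(lm)
  lm2 <- lm
  lm2$frame$voxel_mm <- lm$frame$voxel_mm * 2
  v2 <- compute_volumes(lm2)
  expect_equal(v2$volume_cm3, v1$volume_cm3 * 8)
  expect_identical(v2$voxels, v1$voxels)
})

test_that("asymmetry index is zero for mirrored phantoms and bounded", {
  vr <- compute_volumes(get_fixture("lm_m"))
  vl <- compute_volumes(get_fixture("lm_m_left"))
  asym <- volume_asymmetry(dplyr::bind_rows(vr, vl))
  expect_true(all(abs(asym$asymmetry) < 1e-12))
  # formula bound: L = 2, R = 0 gives +2
  toy <- tibble::tibble(pu = c("X", "X", "Y"),
                        hemisphere = c("left", "right", "left"),
                        volume_cm3 = c(2, 0, 1), voxels = c(2, 0, 1),
                        name = "t", lobe = "t")
  a <- volume_asymmetry(toy)
  expect_equal(a$asymmetry[a$pu == "X"], 2)
  expect_true("Y" %in% attr(a, "skipped"))
})

test_that("packaged reference tables load and answer lookups", {
  rh <- reference_volumes("human")
  rm <- reference_volumes("macaque")
  expect_equal(nrow(rh), 73L)
  expect_equal(nrow(rm), 40L)
  expect_equal(rh$right_cm3[rh$pu == "AGa"], 10.80)
  expect_equal(rh$left_cm3[rh$pu == "AGa"], 12.78)
  expect_equal(rm$left_cm3[rm$pu == "POGm"], 0.10)
  expect_equal(rm$right_cm3[rm$pu == "STRdls"], 1.32)
})

test_that("reference comparison is descriptive and species-checked", {
  vol <- compute_volumes(get_fixture("lm_h"))
  cmp <- compare_to_reference(vol, "human")
  expect_equal(nrow(cmp), 73L)
  expect_true(all(c("diff_cm3", "rel_diff") %in% names(cmp)))
  expect_error(compare_to_reference(vol, "macaque"), class = "hoa_input_error")
})
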