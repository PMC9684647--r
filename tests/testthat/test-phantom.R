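test_that("phantom generation is deterministic and self-consistent", {
  ph <- get_fixture("ph_m")
  ph2 <- generate_phantom(phantom_spec("macaque"))
  expect_identical(ph$hemisphere$ribbon, ph2$hemisphere$ribbon)
  expect_identical(ph$truth$labels, ph2$truth$labels)
  expect_identical(ph$hemisphere$traces, ph2$hemisphere$traces)
})

test_that("ground-truth label maps are valid partitions", {
  for (key in c("ph_h", "ph_m", "ph_h_merged")) {
    ph <- get_fixture(key)
    rep <- check_partition(ph$truth, ph$hemisphere)
    expect_equal(rep$coverage, 1, info = key)
    expect_equal(rep$overlap_count, 0L)
    expect_equal(rep$labels_outside_ribbon, 0L)
  }
})

test_that("phantom annotation is complete for its species' ruleset", {
  expect_silent(check_annotation(get_fixture("ont_h"), get_fixture("ph_h")$hemisphere))
  expect_silent(check_annotation(get_fixture("ont_m"), get_fixture("ph_m")$hemisphere))
})

test_that("the merged fixture carries the combined unit in its ground truth", {
  ph <- get_fixture("ph_h_merged")
  expect_true("FOCL/F3o" %in% ph$truth$lut$pu)
  expect_false(any(c("FOCL", "F3o") %in% ph$truth$lut$pu))
  full <- get_fixture("ph_h")
  expect_true(all(c("FOCL", "F3o") %in% full$truth$lut$pu))
})

test_that("perturbation is identity at zero and refuses excessive jitter", {
  hemi <- get_fixture("ph_m")$hemisphere
  expect_identical(perturb_phantom(hemi, 0), hemi)
  expect_error(perturb_phantom(hemi, 2), class = "hoa_input_error")
  j1 <- perturb_phantom(hemi, 0.4, seed = 3)
  j2 <- perturb_phantom(hemi, 0.4, seed = 3)
  expect_identical(j1$traces, j2$traces)
})

test_that("the fixture catalog covers the degenerate cases", {
  fh <- fixture_suite("human")
  expect_true(all(c("full", "merged_focl", "empty_calc", "left") %in% names(fh)))
  expect_equal(fh$merged_focl$lorb_instances, 1L)
  expect_equal(fh$empty_calc$calc_bank_width, 0L)
  fm <- fixture_suite("macaque")
  expect_true("full" %in% names(fm))
  expect_error(fixture_suite("gibbon"))
})

test_that("mirrored specs generate mirror-image hemispheres", {
  r <- get_fixture("ph_h")
  l <- get_fixture("ph_h_left")
  dmx <- dim(r$hemisphere$ribbon)[1]
  expect_identical(r$hemisphere$ribbon[dmx:1, , ], l$hemisphere$ribbon)
  expect_identical(r$truth$labels[dmx:1, , ], l$truth$labels)
  expect_equal(l$hemisphere$frame$side, "left")
})
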