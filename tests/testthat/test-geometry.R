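frame96 <- hemisphere_frame(c(96, 128, 96), side = "right")

mk_trace <- function(pts) {
  tibble::tibble(sulcus = "t", instance = 1L, point = seq_len(nrow(pts)),
                 x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

test_that("coronal planes sit at the event coordinate, posterior-inclusive", {
  b <- build_coronal_plane(c(50, 37, 40), frame96, id = "CP X")
  expect_equal(b$plane_y, 37L)
  expect_equal(b$meta$side_rule, "posterior-inclusive")
  expect_error(build_coronal_plane(c(50, 500, 40), frame96),
               class = "hoa_geometry_error")
})

test_that("Sylvian 45-degree lines have unit slope on an axis-aligned trace", {
  tr <- mk_trace(cbind(76, 40:90, 43))
  rays <- build_sylvian_opercular_lines(tr, frame96)
  for (r in rays) {
    w <- r$wall
    expect_gt(nrow(w), 5)
    # slope +-1 in the (posterior-anterior, inferior-superior) projection
    dz <- diff(w[, 3]); dy <- diff(w[, 2])
    expect_true(all(abs(dz / dy) == 1))
    expect_equal(r$meta$angle_deg, 45, tolerance = 1e-8)
  }
  expect_gt(rays$superior$wall[2, 3], rays$superior$wall[1, 3])
  expect_lt(rays$inferior$wall[2, 3], rays$inferior$wall[1, 3])
})

test_that("45-degree lines follow a rotated trace direction within 0.5 degrees", {
  # trace climbing anteriorly at 20 degrees
  theta <- 20 * pi / 180
  t <- 0:50
  pts <- cbind(76, round(40 + t * cos(theta)), round(43 + t * sin(theta)))
  rays <- build_sylvian_opercular_lines(mk_trace(pts), frame96)
  analytic <- c(cos(theta), sin(theta))
  for (r in rays) {
    # constructed direction within 0.5 degrees of the analytic 45-degree line
    ang <- acos(abs(sum(r$meta$direction * analytic))) * 180 / pi
    expect_lt(abs(ang - 45), 0.5)
    # rasterized ray within a degree
    w <- r$wall
    realized <- c(w[nrow(w), 2] - w[1, 2], w[nrow(w), 3] - w[1, 3])
    realized <- realized / sqrt(sum(realized^2))
    expect_lt(abs(acos(abs(sum(realized * analytic))) * 180 / pi - 45), 1)
  }
  # near-vertical trace cannot orient the lines
  vert <- mk_trace(cbind(76, 40, 30:60))
  expect_error(build_sylvian_opercular_lines(vert, frame96),
               class = "hoa_geometry_error")
  expect_error(build_sylvian_opercular_lines(mk_trace(cbind(76, 40, 43)), frame96),
               class = "hoa_geometry_error")
})

test_that("calcarine lines flank the trace at the bank width", {
  tr <- mk_trace(cbind(20, 18:39, 34))
  cl <- build_calcarine_lines(tr, frame96, bank_width = 3)
  expect_true(all(cl$superior$wall[, 3] == 37))
  expect_true(all(cl$inferior$wall[, 3] == 31))
  expect_false(cl$superior$meta$degenerate)
  z0 <- build_calcarine_lines(tr, frame96, bank_width = 0)
  expect_true(z0$superior$meta$degenerate)
  expect_true(all(z0$superior$wall[, 3] == 34))
  expect_error(build_calcarine_lines(NULL, frame96, 2), class = "hoa_geometry_error")
})

test_that("supratemporal midline halves the extent", {
  reg <- expand.grid(x = 60:70, y = 10:20, z = 40)
  b <- build_stp_midline(reg, frame96)
  expect_equal(b$plane_y, 15L)
  single <- build_stp_midline(cbind(60, 12, 40), frame96)
  expect_true(single$meta$single_slice)
  expect_error(build_stp_midline(reg[0, ], frame96), class = "hoa_geometry_error")
})

test_that("gyral crest lines bracket the omega apex", {
  ant <- mk_trace(cbind(76, 52, 47:78))
  post <- mk_trace(cbind(76, 48, 47:78))
  gl <- build_gyral_crest_lines(ant, post, c(76, 50, 64), frame96,
                                half_width = 5, prefix = "PRC")
  expect_equal(unique(gl$superior$wall[, 3]), 69)
  expect_equal(unique(gl$inferior$wall[, 3]), 59)
  expect_false(gl$superior$meta$degenerate)
  # apex on the margin: superior line degenerates and is flagged
  high <- build_gyral_crest_lines(ant, post, c(76, 50, 77), frame96, 5, "PRC")
  expect_true(high$superior$meta$degenerate)
  expect_error(build_gyral_crest_lines(ant, post, c(76, 40, 64), frame96, 5, "PRC"),
               class = "hoa_geometry_error")
  expect_error(build_gyral_crest_lines(ant, post, c(76, 50, 48), frame96, 30, "PRC"),
               class = "hoa_geometry_error")
})

test_that("parietal line is the straight geodesic on a flat face", {
  rib <- array(0L, c(96, 128, 96))
  rib[76, 10:60, 10:60] <- .hoa_classes[["lateral"]]
  rib[76, 10:60, 61] <- .hoa_classes[["medial"]]  # keep margin derivable
  b <- build_parietal_line(c(76, 26, 12), c(76, 26, 58),
                           hemisphere_frame(c(96, 128, 96)), rib)
  expect_true(all(b$wall[, 2] == 26))
  expect_equal(b$meta$length, 46)
  expect_gte(b$meta$length, b$meta$euclidean)
  expect_error(build_parietal_line(c(76, 26, 12), c(76, 26, 12),
                                   hemisphere_frame(c(96, 128, 96)), rib),
               class = "hoa_geometry_error")
})

test_that("geodesic length exceeds Euclidean distance across a fold", {
  rib <- array(0L, c(40, 40, 40))
  rib[20, 5:35, 5:20] <- 1L      # lateral wall
  rib[10:20, 5:35, 20] <- 1L     # dorsal shelf
  fr <- hemisphere_frame(c(40, 40, 40))
  b <- build_parietal_line(c(20, 10, 5), c(10, 10, 20), fr, rib)
  expect_gt(b$meta$length, b$meta$euclidean)
})

test_that("hemispheric margin is the lateral-medial fold", {
  rib <- array(0L, c(40, 40, 40))
  rib[30, 5:35, 5:30] <- .hoa_classes[["lateral"]]
  rib[10, 5:35, 5:30] <- .hoa_classes[["medial"]]
  rib[11:29, 5:35, 30] <- rep(c(.hoa_classes[["medial"]], .hoa_classes[["lateral"]]),
                              times = c(9, 10))
  fr <- hemisphere_frame(c(40, 40, 40))
  hm <- derive_hemispheric_margin(rib, fr)
  expect_true(all(hm$wall[, 1] == 20))   # first lateral column on the top face
  expect_true(all(hm$wall[, 3] == 30))
  # disconnected ribbon is rejected
  rib2 <- rib
  rib2[11:29, , ] <- 0L
  expect_error(derive_hemispheric_margin(rib2, fr), class = "hoa_geometry_error")
  expect_error(derive_hemispheric_margin(array(0L, c(4, 4, 4)), fr),
               class = "hoa_geometry_error")
})

test_that("plane construction commutes with frame permutation of the y axis", {
  # reflecting the posterior-anterior axis then building equals building
  # then reflecting
  ev <- c(50, 37, 40)
  dm <- frame96$dim
  refl <- function(y) dm[2] + 1 - y
  b1 <- build_coronal_plane(c(ev[1], refl(ev[2]), ev[3]), frame96)
  b2 <- build_coronal_plane(ev, frame96)
  expect_equal(b1$plane_y, refl(b2$plane_y))
})
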