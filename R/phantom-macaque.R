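#' @title Synthetic macaque phantom hemisphere
#' @name phantom_macaque
#' @description
#' The macaque phantom mirrors the human folded-slab design at a smaller
#' scale: a box shell with a Sylvian slot, two opercular shelves (the lower
#' one is the supratemporal plane), an insular wall, callosal and
#' subcortical openings, an arcuate sulcus with superior and inferior
#' limbs anchoring the ASL/APL derived lines, and calcarine/ectocalcarine
#' grooves that wrap onto the occipital pole face.
NULL

mp_const <- function() {
  list(
    dim = c(64L, 80L, 64L),
    x_med = 12L, x_lat = 52L, hm_x = 32L,
    z_vent = 12L, z_dors = 52L,
    y0 = 6L, y1 = 74L,
    slot_z = c(22L, 26L), slot_y = c(14L, 56L),
    shelf_x0 = 40L, shelf_y = c(14L, 48L),
    insula_y = c(28L, 48L), insula_z = c(23L, 25L),
    A = 66L, B = 52L, C = 56L, D = 44L, E = 44L, F = 34L, G = 30L,
    H = 28L, I = 26L, J = 17L, K = 18L, L = 13L, M = 40L, BF = 49L,
    cgs_z = 42L, cas_z = 37L, ros_z = 30L, ccs_z = 20L, sccs_z = 44L,
    ecs_z = 36L, iocs_z = 13L, prs_z = 32L, itps_z = 38L, sts_z = 17L,
    arc_z = 40L, lus_y = 18L, pos_y = 13L, sbps_y = 26L,
    olfs_x = 18L, mos_x = 24L, los_x = 32L, tos_y = 58L,
    ots_x = 26L, hpc_x = 13L
  )
}

mp_lines <- function(k) {
  list(
    ce_y = function(z) as.integer(round(30 + 4 * (52 - z) / 25)),
    plc_y = function(z) if (z <= 32) 15L else 16L,
    plb_z = function(y) as.integer(round(14 + 3 * (pmax(pmin(y, 24), 17) - 17) / 7))
  )
}

mp_ribbon <- function(k) {
  rib <- array(0L, k$dim)
  cls <- .hoa_classes
  rib[k$x_med, 6:74, 12:52] <- cls[["medial"]]
  rib[k$x_med, 50:66, 12:29] <- cls[["ventral"]]   # gyrus rectus wall
  rib[k$x_med, 67:74, 12:26] <- 0L
  rib[k$x_med, 26:54, 30:36] <- 0L                 # corpus callosum
  rib[k$x_med, 14:49, 12:29] <- 0L                 # subcortical opening
  rib[k$x_lat, 6:74, 12:52] <- cls[["lateral"]]
  rib[k$x_lat, 14:56, 22:26] <- 0L                 # Sylvian slot
  rib[k$x_lat, 57:74, 12:26] <- 0L
  rib[13:32, 6:74, k$z_dors] <- cls[["medial"]]
  rib[33:51, 6:74, k$z_dors] <- cls[["lateral"]]
  rib[13:51, 6:44, k$z_vent] <- cls[["ventral"]]
  rib[13:51, 50:66, k$z_vent] <- cls[["ventral"]]
  rib[13:26, 18:26, k$z_vent] <- 0L                # hippocampal recess
  rib[13:32, k$y1, 27:51] <- cls[["medial"]]
  rib[33:51, k$y1, 27:51] <- cls[["lateral"]]
  rib[13:32, k$y0, 13:51] <- cls[["medial"]]
  rib[33:51, k$y0, 13:51] <- cls[["lateral"]]
  rib[40:52, 14:48, 26] <- cls[["opercular"]]      # frontoparietal operculum
  rib[42:52, 14:48, 22] <- cls[["opercular"]]      # supratemporal plane
  rib[40, 28:48, 23:25] <- cls[["insular"]]
  rib
}

mp_truth_fun <- function(k, bank_width) {
  ln <- mp_lines(k)
  b <- bank_width

  med <- function(y, z) {
    if (y > 66) return("FP")
    if (z > 42) {
      if (y > 52) "F1dm" else if (y > 40) "PreSMA" else if (y > 30) "PRGm/SMA"
      else if (y > 26) "POGm" else if (y > 17) "CGp" else if (y > 13) "MPC" else "STRm"
    } else if (z > 36) {
      if (y > 30) "CGa" else if (y > 17) "CGp" else if (y > 13) "MPC" else "STRm"
    } else if (z > 29) {
      if (y > 55) { if (z == 30) "FMC" else "CGa" }
      else if (y == 55) "CGa"
      else if (y > 17) "CGp"
      else if (y > 13) "MPC"
      else "STRm"
    } else if (z > k$ccs_z + b) {
      if (y > 56) "FMC" else if (y > 49) "SC" else "STRm"
    } else if (z > k$ccs_z) {
      if (y > 56) "FMC" else if (y > 49) "SC" else "CALCs"
    } else if (z == k$ccs_z) {
      if (y > 56) "FMC" else if (y > 49) "SC" else if (b > 0) "CALCi" else "STRdli"
    } else if (z > k$ccs_z - b) {
      if (y > 56) "FMC" else if (y > 49) "SC" else "CALCi"
    } else {
      if (y > 56) "FMC" else if (y > 49) "SC" else "STRdli"
    }
  }

  lat_upper <- function(y, z) {   # z in 27..52
    cey <- ln$ce_y(z); plc <- ln$plc_y(z)
    if (y > 66) "FP"
    else if (y > 52) { if (z > 40) "F1dls" else if (z > 32) "F1dli" else "F2" }
    else if (y > 44) { if (z >= 40) "PMd" else if (z > 32) "F1dli" else "F2" }
    else if (y > 40) { if (z >= 40) "PMd" else "PMv" }
    else if (y > cey) "PRGL"
    else if (y >= 28) "POGL"
    else if (y == 27) { if (z > 38) "LPCs" else "LPCi" }
    else if (y > 17) { if (z > 38) "LPCs" else "LPCi" }
    else if (y > plc && z < 38) "LPCi"
    else if (z > 36) "STRdls"
    else "STRdli"
  }

  lat_lower <- function(y, z) {   # z in 12..21
    if (y > 44) "TP"
    else if (y > 24) { if (z > 17) "STG" else "ITG" }
    else if (y > 18) { if (z > ln$plb_z(y)) "PRL" else "ITG" }
    else "STRdli"
  }

  vent <- function(x, y) {
    if (y >= 50) {
      if (x <= k$olfs_x) { if (y > 56) "FMC" else "SC" }
      else if (x <= k$mos_x) "FOCm"
      else if (x <= k$los_x) { if (y > k$tos_y) "FOCa" else "FOCp" }
      else "FOCL"
    } else if (y > 17) {
      if (x <= k$ots_x) "PH" else "ITG"
    } else if (y > 13) "VMO" else "STRdli"
  }

  dors <- function(x, y) {
    if (x >= 33) {
      if (y > 66) "FP" else if (y > 52) "F1dls" else if (y > 40) "PMd"
      else if (y > 30) "PRGL" else if (y >= 28) "POGL" else if (y > 17) "LPCs"
      else "STRdls"
    } else {
      if (y > 66) "FP" else if (y > 52) "F1dm" else if (y > 40) "PreSMA"
      else if (y > 30) "PRGm/SMA" else if (y > 26) "POGm" else if (y > 17) "CGp"
      else if (y > 13) "MPC" else "STRm"
    }
  }

  pole_post <- function(x, z) {
    if (x >= 33) { if (z > 36) "STRdls" else "STRdli" }
    else {
      if (z > 22) "STRm"
      else if (z > k$ccs_z) "CALCs" else if (z > 18) "CALCi"
      else if (z == k$ccs_z) { if (b > 0) "CALCi" else "STRdli" }
      else "STRdli"
    }
  }

  shelf_sup <- function(x, y) if (y > 34) "COa" else if (y > 27) "COp" else "PO"
  shelf_inf <- function(x, y) if (y > 44) "TP" else if (y > 31) "STPa" else "STPp"

  function(x, y, z, cls) {
    if (cls == .hoa_classes[["opercular"]]) {
      return(if (z == 26L) shelf_sup(x, y) else shelf_inf(x, y))
    }
    if (cls == .hoa_classes[["insular"]]) return("INS")
    if (x == k$x_med) return(med(y, z))
    if (x == k$x_lat) {
      if (z >= 27) return(lat_upper(y, z))
      return(lat_lower(y, z))
    }
    if (z == k$z_dors) return(dors(x, y))
    if (z == k$z_vent) return(vent(x, y))
    if (y == k$y1) return("FP")
    if (y == k$y0) return(pole_post(x, z))
    stop(sprintf("unclassified phantom voxel (%d, %d, %d)", x, y, z))
  }
}

mp_traces <- function(k) {
  tr <- list()
  add <- function(sulcus, pts, instance = 1L) {
    pts <- unique(pts)
    tr[[length(tr) + 1L]] <- tibble(sulcus = sulcus, instance = instance,
                                    point = seq_len(nrow(pts)),
                                    x = pts[, 1], y = pts[, 2], z = pts[, 3])
    assign("tr", tr, envir = parent.frame())
  }
  env <- environment()
  add <- function(sulcus, pts, instance = 1L) {
    pts <- unique(pts)
    env$tr[[length(env$tr) + 1L]] <- tibble(sulcus = sulcus, instance = instance,
                                            point = seq_len(nrow(pts)),
                                            x = pts[, 1], y = pts[, 2], z = pts[, 3])
  }
  ln <- mp_lines(k)
  xl <- k$x_lat; xm <- k$x_med
  add("ce", rbind(t(vapply(27:52, function(z) c(xl, ln$ce_y(z), z), numeric(3))),
                  cbind(33:51, 30, k$z_dors)))
  add("arc", rbind(cbind(xl, 44:52, k$arc_z), cbind(xl, 44, 27:40)))
  add("prs", cbind(xl, 44:66, k$prs_z))
  add("itps", cbind(xl, 17:28, k$itps_z))
  add("lf", cbind(xl, 14:48, 26))
  add("sts", rbind(cbind(xl, 24:44, k$sts_z), cbind(xl, 24, 17:21)))
  add("lus", rbind(cbind(xl, k$lus_y, 27:52), cbind(33:51, k$lus_y, k$z_dors)))
  add("ecs", rbind(cbind(xl, 6:17, k$ecs_z), cbind(33:51, 6, k$ecs_z)))
  add("iocs", rbind(cbind(xl, 8:17, k$iocs_z), cbind(xl, 8:17, 12)))
  add("cgs", cbind(xm, 27:66, k$cgs_z))
  add("cas", rbind(cbind(xm, 25:55, k$cas_z), cbind(xm, 55, 30:37),
                   cbind(xm, 25, 30:36)))
  add("ros", cbind(xm, 55:66, k$ros_z))
  add("ccs", rbind(cbind(xm, 6:13, k$ccs_z), cbind(13:32, 6, k$ccs_z)))
  add("sccs", rbind(cbind(xm, 6:13, k$sccs_z), cbind(13:32, 6, k$sccs_z)))
  add("pos", cbind(xm, k$pos_y, 22:44))
  add("sbps", cbind(xm, k$sbps_y, 30:38))
  add("olfs", cbind(k$olfs_x, 50:66, k$z_vent))
  add("mos", cbind(k$mos_x, 50:66, k$z_vent))
  add("los", cbind(k$los_x, 50:66, k$z_vent))
  add("tos", cbind(25:31, k$tos_y, k$z_vent))
  add("ots", cbind(k$ots_x, 27:36, k$z_vent))
  add("rhs", cbind(k$ots_x, 37:44, k$z_vent))
  add("hpc", cbind(k$hpc_x, 27:44, k$z_vent))
  bind_rows(env$tr)
}

mp_events <- function(k) {
  ev <- function(landmark, x, y, z) tibble(landmark = landmark, x = x, y = y, z = z)
  bind_rows(
    ev("CP A", k$x_lat, k$A, k$prs_z),
    ev("CP B", k$x_lat, k$B, k$arc_z),
    ev("CP C", k$x_med, k$C, k$cas_z),
    ev("CP D", k$x_lat, k$D, 27),
    ev("CP E", 40, k$E, 22),
    ev("CP F", k$x_lat, k$F, 27),
    ev("CP G", k$x_lat, k$G, k$z_dors),
    ev("CP H", k$x_lat, k$H, k$itps_z),
    ev("CP I", k$x_med, k$I, 21),
    ev("CP J", k$x_lat, k$J, k$iocs_z),
    ev("CP K", k$x_lat, k$K, 27),
    ev("CP L", k$x_med, k$L, 22),
    ev("CP M", k$x_med, k$M, 38),
    ev("BF", k$olfs_x, k$BF, k$z_vent),
    ev("Pl a", k$x_med, k$sbps_y, 45),
    ev("Pl b", k$x_lat, 17, 14), ev("Pl b", k$x_lat, 24, 17),
    ev("Pl c", k$x_lat, 15, 27), ev("Pl c", k$x_lat, 16, 38)
  )
}

generate_macaque_phantom <- function(spec) {
  k <- mp_const()
  bank <- spec$calc_bank_width %||% 2L
  frame <- hemisphere_frame(k$dim, side = "right")
  rib <- mp_ribbon(k)
  hemi <- annotated_hemisphere(frame, rib, mp_traces(k), mp_events(k), "macaque",
                               params = list(calc_bank_width = bank))
  ont <- load_ontology("macaque")
  units <- ont$units |> arrange(.data$row)
  code_of <- setNames(seq_len(nrow(units)), units$id)
  tf <- mp_truth_fun(k, bank)
  vox <- which(rib > 0L, arr.ind = TRUE)
  labs <- integer(nrow(vox))
  for (i in seq_len(nrow(vox))) {
    labs[i] <- code_of[[tf(vox[i, 1], vox[i, 2], vox[i, 3],
                           rib[vox[i, 1], vox[i, 2], vox[i, 3]])]]
  }
  truth_arr <- array(0L, k$dim)
  truth_arr[vox] <- labs
  lut <- tibble(code = seq_len(nrow(units)), pu = units$id, name = units$name,
                lobe = units$lobe, side = "right")
  empty <- units$id[!(seq_len(nrow(units)) %in% unique(labs))]
  truth <- new_labelmap(frame, truth_arr, lut, "macaque", empty_units = empty,
                        provenance = list(source = "phantom"))
  if (identical(spec$side, "left")) {
    hemi <- mirror_x(hemi)
    truth <- mirror_labelmap(truth)
  }
  list(hemisphere = hemi, truth = truth)
}
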