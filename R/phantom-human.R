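#' @title Synthetic human phantom hemisphere
#' @name phantom_human
#' @description
#' The human phantom is a folded-slab hemisphere: a box shell with lateral,
#' medial, ventral (orbital and temporo-occipital), dorsal and pole faces, a
#' Sylvian slot with two opercular shelves and an insular wall, a callosal
#' and a subcortical opening in the medial wall, and rectilinear sulcal
#' grooves placed so that every border symbol of the 73-unit ruleset is
#' exercised. All placements are fixed design constants of the phantom, so
#' the ground-truth label of every ribbon voxel is known analytically.
NULL

# Design constants of the human phantom (canonical right hemisphere).
hp_const <- function() {
  list(
    dim = c(96L, 128L, 96L),
    x_med = 20L, x_lat = 76L, hm_x = 48L,
    z_vent = 18L, z_dors = 78L,
    y0 = 10L, y1 = 118L,
    slot_z = c(40L, 46L), slot_y = c(38L, 108L),
    shelf_x0 = 60L,
    insula_y = c(44L, 100L), insula_z = c(41L, 45L),
    # coronal plane anchors (posterior-anterior voxel coordinate)
    G = 18L, PAL = 26L, F = 30L, E = 34L, D = 38L, N = 40L, He = 42L,
    C = 42L, ftr = 46L, L = 48L, P = 48L, M = 52L, K = 52L, R = 52L,
    O = 56L, J = 72L, B = 70L, SEP = 79L, BF = 79L, I = 89L, H = 100L,
    Q = 108L, A = 104L,
    # medial-face landmarks
    ci_z = 62L, pa_z = 68L, ca_z = 53L, sp_y = 43L, ma_y = 44L,
    ci_ant = 96L, pa_ant = 100L, ca_ant = 89L, ca_post = 45L,
    calc_z = 34L, cun_z = 44L,
    # lateral-face landmarks
    sf_z = 68L, if_z = 56L, ahr_z = 50L, aar_y = 84L, ip_z = 56L,
    im_y = 34L, st_z = 32L, lo_z = 32L, it_z = 26L,
    # ventral-face landmarks
    ol_x = 30L, morb_x = 40L, lorb_x = 50L, lorb2_x = 62L, torb_y = 94L,
    co_x = 44L, ot_x = 56L, hi_x = 21L, cei_y = 62L,
    omega_z = 64L
  )
}

hp_lines <- function(k) {
  list(
    prc_y = function(z) as.integer(round(52 + 4 * (78 - z) / 31)),
    ce_y = function(z) as.integer(round(48 + 4 * (78 - z) / 31)),
    pcs_y = function(z) as.integer(round(44 + 4 * (78 - z) / 31)),
    po_y = function(z) as.integer(round(40 - 14 * (z - 38) / 40))
  )
}

hp_ribbon <- function(k) {
  rib <- array(0L, k$dim)
  cls <- .hoa_classes
  # medial wall
  rib[k$x_med, k$y0:k$y1, k$z_vent:k$z_dors] <- cls[["medial"]]
  rib[k$x_med, 80:108, 18:39] <- cls[["ventral"]]      # gyrus rectus wall
  rib[k$x_med, 109:118, 18:46] <- 0L                   # frontal pole rounding
  rib[k$x_med, 46:88, 40:52] <- 0L                     # corpus callosum
  rib[k$x_med, 40:78, 18:39] <- 0L                     # subcortical opening
  # lateral wall
  rib[k$x_lat, k$y0:k$y1, k$z_vent:k$z_dors] <- cls[["lateral"]]
  rib[k$x_lat, 38:108, 40:46] <- 0L                    # Sylvian slot
  rib[k$x_lat, 75:118, 18:39] <- 0L                    # no cortex below anterior Sylvian stem
  rib[k$x_lat, 109:118, 40:46] <- 0L
  # dorsal face
  rib[21:48, k$y0:k$y1, k$z_dors] <- cls[["medial"]]
  rib[49:75, k$y0:k$y1, k$z_dors] <- cls[["lateral"]]
  # ventral face (temporo-occipital and orbital sheets)
  rib[21:75, 10:74, k$z_vent] <- cls[["ventral"]]
  rib[21:75, 80:108, k$z_vent] <- cls[["ventral"]]
  # anterior and posterior pole faces
  rib[21:48, k$y1, 47:77] <- cls[["medial"]]
  rib[49:75, k$y1, 47:77] <- cls[["lateral"]]
  rib[21:48, k$y0, 19:77] <- cls[["medial"]]
  rib[49:75, k$y0, 19:77] <- cls[["lateral"]]
  # opercular shelves and insular wall
  rib[60:76, 38:108, 46] <- cls[["opercular"]]
  rib[60:76, 38:74, 40] <- cls[["opercular"]]
  rib[60, 44:100, 41:45] <- cls[["insular"]]
  rib
}

# Analytic ground truth: label of one voxel, given its face.
hp_truth_fun <- function(k, bank_width, merged) {
  ln <- hp_lines(k)
  b <- bank_width
  focl <- if (merged) "FOCL/F3o" else "FOCL"
  f3o_orb <- if (merged) "FOCL/F3o" else "F3o"

  lat_upper <- function(y, z) {
    if (y > 108) return("FPL")
    p <- ln$prc_y(z); cc <- ln$ce_y(z); q <- ln$pcs_y(z)
    if (y > p) {
      if (z > 68) { if (y > 89) "F1La" else if (y > 56) "F1Lm" else "F1Lp" }
      else if (z > 56) { if (y > 89) "F2a" else if (y > 56) "F2m" else "F2p" }
      else {
        if (y > 104) { if (z > 50) "F3a" else "F3orb" }
        else if (y > 84) "F3t"
        else f3o_orb
      }
    } else if (y > cc) {
      if (z > 69) "PRGLs" else if (z > 59) "PRGLm" else "PRGLi"
    } else if (y > q) {
      if (z > 69) "POGLs" else if (z > 59) "POGLm" else "POGLi"
    } else if (y > 38) {
      if (z > 56) "SPLa" else "SGa"
    } else if (y > 34) {
      if (z > 56) "SPLa" else "SGp"
    } else if (y > 30) {
      if (z > 56) "SPLa" else "AGa"
    } else if (y > 26) {
      if (z > 56) "SPLp" else "AGp"
    } else if (y > 18) "OLs" else "OP"
  }

  lat_mid <- function(y, z) {   # z in slot range, posterior of the slot
    if (y > 34) "SGp" else if (y > 30) "AGa" else if (y > 26) "AGp"
    else if (y > 18) "OLs" else "OP"
  }

  lat_lower <- function(y, z) {
    if (y > 70) return("TP")
    if (z > 32) {
      if (y > 42) "T1a" else if (y > 38) "T1p" else if (y > 34) "SGp"
      else if (y > 30) "AGa" else if (y > 26) "AGp" else if (y > 18) "OLs" else "OP"
    } else if (z > 26) {
      if (y > 42) "T2a" else if (y > 38) "T2p" else if (y > 30) "TO2"
      else if (y > 18) "OLi" else "OP"
    } else {
      if (y > 42) "T3a" else if (y > 38) "T3p" else if (y > 30) "TO3"
      else if (y > 18) "OLi" else "OP"
    }
  }

  vent <- function(x, y) {
    if (y >= 80) {                      # orbital sheet
      if (x <= 30) { if (y > 89) "FMC" else "SC" }
      else if (x <= 40) "FOCm"
      else if (x <= 50) { if (y > 94) "FOCa" else "FOCp" }
      else if (merged) "FOCL/F3o"
      else if (x <= k$lorb2_x) focl
      else f3o_orb
    } else {                            # temporo-occipital sheet
      if (y > 70) return("TP")
      if (x <= 44) {
        if (y > 52) "PHa" else if (y > 40) "PHp" else if (y > 18) "LG" else "OP"
      } else if (x <= 56) {
        if (y > 42) "TFa" else if (y > 38) "TFp" else if (y > 30) "TOF"
        else if (y > 18) "OF" else "OP"
      } else {
        if (y > 42) "T3a" else if (y > 38) "T3p" else if (y > 30) "TO3"
        else if (y > 18) "OLi" else "OP"
      }
    }
  }

  med <- function(y, z) {
    if (y > 108) return("FPm")
    if (y > 100) return(if (z >= 40) "FPm" else "FMC")
    if (y > 89) {
      if (z > 68) "F1m"
      else if (z > 62) "PAC"
      else if (z >= 40) { if (y > 96) "PAC" else "CGa_a" }
      else "FMC"
    } else if (y > 79) {
      if (z > 68) "PreSMAs" else if (z > 62) "PreSMAi"
      else if (z > 52) "CGa_p" else if (z >= 40) "SC" else "SC"
    } else if (y > 72) {
      if (z > 68) "PreSMAs" else if (z > 62) "PreSMAi" else "CGa_p"
    } else if (y > 52) {
      if (z > 62) "SMA" else "CGa_p"
    } else if (y > 48) {
      if (z > 62) "PRGm" else "CGp"
    } else if (y > 43) {
      if (z > 62) "POGm" else "CGp"
    } else if (z >= 38 && y > ln$po_y(z)) {
      "PCN"
    } else {
      if (z > 44) { if (y > 18) "CN" else "OP" }
      else if (z > k$calc_z + b) { if (y > 18) "SCALC" else "OP" }
      else if (z > k$calc_z) { if (y > 18) "CALCs" else "OP" }
      else if (z == k$calc_z) { if (y > 18) { if (b > 0) "CALCi" else "LG" } else "OP" }
      else if (z > k$calc_z - b) { if (y > 18) "CALCi" else "OP" }
      else { if (y > 18) "LG" else "OP" }
    }
  }

  dors <- function(x, y) {
    if (x >= 49) {
      if (y > 108) "FPL" else if (y > 89) "F1La" else if (y > 56) "F1Lm"
      else if (y > 52) "F1Lp" else if (y > 48) "PRGLs" else if (y > 44) "POGLs"
      else if (y > 30) "SPLa" else if (y > 26) "SPLp" else if (y > 18) "OLs" else "OP"
    } else {
      if (y > 100) "FPm" else if (y > 89) "F1m" else if (y > 72) "PreSMAs"
      else if (y > 52) "SMA" else if (y > 48) "PRGm" else if (y > 43) "POGm"
      else if (y > 26) "PCN" else if (y > 18) "CN" else "OP"
    }
  }

  shelf_sup <- function(x, y) {
    if (y > 56) "FO" else if (y > 52) "COa" else if (y > 48) "COp" else "PO"
  }
  shelf_inf <- function(x, y) {
    if (y > 70) "TP" else if (y > 46) "PP" else if (y > 42) "H1" else "PT"
  }
  insula <- function(y, z) if (y > k$cei_y) "INSa" else "INSp"

  function(x, y, z, cls) {
    if (x == k$x_med) return(med(y, z))
    if (cls == .hoa_classes[["opercular"]]) {
      return(if (z == 46L) shelf_sup(x, y) else shelf_inf(x, y))
    }
    if (cls == .hoa_classes[["insular"]]) return(insula(y, z))
    if (x == k$x_lat) {
      if (z >= 47) return(lat_upper(y, z))
      if (z >= 40) return(lat_mid(y, z))
      return(lat_lower(y, z))
    }
    if (z == k$z_dors) return(dors(x, y))
    if (z == k$z_vent) return(vent(x, y))
    if (y == k$y1) return(if (x >= 49) "FPL" else "FPm")
    if (y == k$y0) return("OP")
    stop(sprintf("unclassified phantom voxel (%d, %d, %d)", x, y, z))
  }
}

hp_traces <- function(k, lorb_instances) {
  tr <- list()
  add <- function(sulcus, pts, instance = 1L) {
    pts <- unique(pts)
    tr[[length(tr) + 1L]] <<- tibble(sulcus = sulcus, instance = instance,
                                     point = seq_len(nrow(pts)),
                                     x = pts[, 1], y = pts[, 2], z = pts[, 3])
  }
  ln <- hp_lines(k)
  xl <- k$x_lat; xm <- k$x_med
  hseg <- function(x, ys, z) cbind(x, ys, z)
  vseg <- function(x, y, zs) cbind(x, y, zs)

  # lateral wall
  add("sf", hseg(xl, 52:108, k$sf_z))
  add("if", hseg(xl, 52:108, k$if_z))
  add("ahr", hseg(xl, 105:108, k$ahr_z))
  add("aar", vseg(xl, k$aar_y, 47:56))
  add("prs", rbind(t(vapply(47:78, function(z) c(xl, ln$prc_y(z), z), numeric(3))),
                   hseg(49:75, 52, k$z_dors)))
  add("ce", rbind(t(vapply(47:78, function(z) c(xl, ln$ce_y(z), z), numeric(3))),
                  hseg(49:75, 48, k$z_dors)))
  add("pcs", rbind(t(vapply(47:78, function(z) c(xl, ln$pcs_y(z), z), numeric(3))),
                   hseg(49:75, 44, k$z_dors)))
  add("ip", hseg(xl, 24:48, k$ip_z))
  add("im", vseg(xl, k$im_y, 32:56))
  add("st", hseg(xl, 26:70, k$st_z))
  add("lo", hseg(xl, 18:26, k$lo_z))
  add("it", hseg(xl, 30:70, k$it_z))
  add("phr", hseg(xl, 38:106, 46))
  # medial wall
  add("ci", rbind(hseg(xm, 44:96, k$ci_z), vseg(xm, k$ci_ant, 40:62),
                  vseg(xm, k$ma_y, 62:78), hseg(21:48, k$ma_y, k$z_dors)))
  add("pa", rbind(hseg(xm, 73:100, k$pa_z), vseg(xm, k$pa_ant, 40:68)))
  add("ca", rbind(hseg(xm, 45:89, k$ca_z), vseg(xm, k$ca_ant, 40:53),
                  vseg(xm, k$ca_post, 40:53)))
  add("sp", rbind(vseg(xm, k$sp_y, 38:78), hseg(21:48, k$sp_y, k$z_dors)))
  add("po", rbind(t(vapply(38:78, function(z) c(xm, ln$po_y(z), z), numeric(3))),
                  hseg(21:48, k$PAL, k$z_dors)))
  add("calc", hseg(xm, 18:39, k$calc_z))
  add("cun", hseg(xm, 18:39, k$cun_z))
  # ventral sheets
  add("ol", hseg(k$ol_x, 80:108, k$z_vent))
  add("morb", hseg(k$morb_x, 80:108, k$z_vent))
  add("lorb", hseg(k$lorb_x, 80:108, k$z_vent))
  if (lorb_instances >= 2L) add("lorb", hseg(k$lorb2_x, 80:108, k$z_vent), instance = 2L)
  add("torb", cbind(41:49, k$torb_y, k$z_vent))
  add("co", hseg(k$co_x, 10:70, k$z_vent))
  add("ot", hseg(k$ot_x, 10:70, k$z_vent))
  add("hi", hseg(k$hi_x, 40:70, k$z_vent))
  # opercular shelves and insula
  add("He", cbind(60:76, k$He, 40))
  add("ftr", cbind(60:76, k$ftr, 40))
  add("cei", vseg(60, k$cei_y, 41:45))
  bind_rows(tr)
}

hp_events <- function(k) {
  ev <- function(landmark, x, y, z) tibble(landmark = landmark, x = x, y = y, z = z)
  bind_rows(
    ev("CP A", k$x_lat, k$A, k$ahr_z),
    ev("CP B", k$x_lat, k$B, 30),
    ev("CP C", 66, k$C, 40),
    ev("CP D", k$x_lat, k$D, 46),
    ev("CP E", k$x_lat, k$E, 32),
    ev("CP F", k$x_lat, k$F, k$ip_z),
    ev("CP G", k$x_med, k$G, k$cun_z),
    ev("CP H", k$x_med, k$H, k$pa_z),
    ev("CP I", k$x_med, k$I, k$ca_z),
    ev("CP J", k$x_med, k$J, 60),
    ev("CP K", k$x_lat, k$K, k$z_dors),
    ev("CP L", k$x_lat, k$L, k$z_dors),
    ev("CP M", k$x_med, k$M, 30),
    ev("CP N", k$x_med, k$N, k$calc_z + 1L),
    ev("CP O", k$x_lat, k$O, 47),
    ev("CP P", k$x_lat, k$P, 47),
    ev("CP Q", k$ol_x, k$Q, k$z_vent),
    ev("CP R", k$x_lat, k$R, 47),
    ev("BF", k$ol_x, k$BF, k$z_vent),
    ev("SEP", k$x_med, k$SEP, 30),
    ev(.aux_events[["omega_prc"]], k$x_lat, 52, k$omega_z),
    ev(.aux_events[["omega_poc"]], k$x_lat, 48, k$omega_z),
    ev(.aux_events[["pon"]], k$x_lat, k$PAL, k$z_vent),
    ev(.aux_events[["po_sup"]], k$hm_x, k$PAL, k$z_dors)
  )
}

generate_human_phantom <- function(spec) {
  k <- hp_const()
  lorb_instances <- spec$lorb_instances %||% 2L
  bank <- spec$calc_bank_width %||% 3L
  omega_w <- spec$omega_half_width %||% 5L
  merged <- lorb_instances < 2L

  frame <- hemisphere_frame(k$dim, side = "right")
  rib <- hp_ribbon(k)
  traces <- hp_traces(k, lorb_instances)
  events <- hp_events(k)
  hemi <- annotated_hemisphere(frame, rib, traces, events, "human",
                               params = list(calc_bank_width = bank,
                                             omega_half_width = omega_w))

  ont <- load_ontology("human")
  eff <- if (merged) apply_focl_f3o_merge(ont, hemi) else ont
  units <- eff$units |> arrange(.data$row)
  code_of <- setNames(seq_len(nrow(units)), units$id)

  tf <- hp_truth_fun(k, bank, merged)
  vox <- which(rib > 0L, arr.ind = TRUE)
  labs <- integer(nrow(vox))
  for (i in seq_len(nrow(vox))) {
    id <- tf(vox[i, 1], vox[i, 2], vox[i, 3], rib[vox[i, 1], vox[i, 2], vox[i, 3]])
    labs[i] <- code_of[[id]]
  }
  truth_arr <- array(0L, k$dim)
  truth_arr[vox] <- labs
  lut <- tibble(code = seq_len(nrow(units)), pu = units$id, name = units$name,
                lobe = units$lobe, side = "right")
  empty <- units$id[!(seq_len(nrow(units)) %in% unique(labs))]
  truth <- new_labelmap(frame, truth_arr, lut, "human", empty_units = empty,
                        provenance = list(source = "phantom", merged = merged))
  if (identical(spec$side, "left")) {
    hemi <- mirror_x(hemi)
    truth <- mirror_labelmap(truth)
  }
  list(hemisphere = hemi, truth = truth)
}
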