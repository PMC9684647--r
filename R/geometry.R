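#' @title Border geometry primitives
#' @name geometry
#' @description
#' Every border named in the parcellation rules is realized as concrete
#' geometry in the hemisphere frame: coronal limiting planes anchored at
#' landmark events, sulcal traces voxelized as blocking walls, and derived
#' lines (45-degree Sylvian lines, calcarine bank lines, pre/postcentral
#' omega lines, the parietal line, the macaque arcuate lines, the
#' supratemporal-plane midline, the hemispheric margin). Planes use a
#' half-open ownership convention: the plane's own coordinate belongs to the
#' posterior region, so two units sharing a plane tile the strip exactly.
NULL

# Surface classes of ribbon voxels. The hemispheric margin is the fold
# between lateral- and medial-class voxels; the Sylvian lips are the folds
# between lateral- and opercular-class voxels.
.hoa_classes <- c(lateral = 1L, medial = 2L, ventral = 3L, opercular = 4L,
                  insular = 5L)

new_border <- function(id, kind, wall = NULL, plane_y = NULL, meta = list()) {
  structure(list(id = id, kind = kind, wall = wall, plane_y = plane_y,
                 meta = meta), class = "hoa_border")
}

#' @export
print.hoa_border <- function(x, ...) {
  desc <- if (!is.null(x$plane_y)) sprintf("y = %d (posterior-inclusive)", x$plane_y)
  else if (!is.null(x$wall)) sprintf("%d wall voxels", nrow(x$wall))
  else "implicit"
  cat(sprintf("<hoa_border> %s [%s]: %s\n", x$id, x$kind, desc))
  invisible(x)
}

# Integer staircase between two points in a 2-D plane: consecutive points
# differ by at most 1 in each coordinate, so a 6-connected path cannot slip
# through the voxelized line.
staircase2 <- function(a, b) {
  n <- max(abs(b - a)) + 1L
  if (n == 1L) return(matrix(a, ncol = 2))
  t <- seq(0, 1, length.out = n)
  cbind(round(a[1] + t * (b[1] - a[1])), round(a[2] + t * (b[2] - a[2])))
}

as_point <- function(p) {
  if (is.data.frame(p)) p <- unlist(p[1, c("x", "y", "z")])
  as.numeric(p[1:3])
}

in_frame <- function(frame, pts) {
  pts[, 1] >= 1 & pts[, 1] <= frame$dim[1] &
    pts[, 2] >= 1 & pts[, 2] <= frame$dim[2] &
    pts[, 3] >= 1 & pts[, 3] <= frame$dim[3]
}

#' Build a coronal limiting plane from a landmark event
#'
#' @param event A landmark event: anything with `x`, `y`, `z` voxel
#'   coordinates (tibble row or numeric vector), optionally a `landmark` id.
#' @param frame A [hemisphere_frame()].
#' @param ribbon Optional ribbon class array; if given, the event must fall
#'   inside its bounding box.
#' @param id Border id; defaults to the event's landmark id.
#' @return An `hoa_border` of kind `"coronal-plane"` whose `plane_y` is the
#'   event's posterior-anterior coordinate. The plane blocks growth between
#'   `y = plane_y` and `y = plane_y + 1`; the plane coordinate itself
#'   belongs to the posterior side.
#' @export
build_coronal_plane <- function(event, frame, ribbon = NULL, id = NULL) {
  p <- as_point(event)
  if (is.null(id)) {
    id <- if (is.data.frame(event) && "landmark" %in% names(event)) event$landmark[1] else "plane"
  }
  if (any(p < 1) || any(p > frame$dim)) {
    abort(sprintf("Landmark event for %s lies outside the frame.", id),
          class = "hoa_geometry_error")
  }
  if (!is.null(ribbon)) {
    idx <- which(ribbon > 0L, arr.ind = TRUE)
    bb_lo <- apply(idx, 2, min); bb_hi <- apply(idx, 2, max)
    if (any(p < bb_lo) || any(p > bb_hi)) {
      abort(sprintf("Landmark event for %s lies outside the ribbon bounding box.", id),
            class = "hoa_geometry_error")
    }
  }
  new_border(id, "coronal-plane", plane_y = as.integer(round(p[2])),
             meta = list(side_rule = "posterior-inclusive"))
}

trace_points <- function(trace) {
  as.matrix(trace[order(trace$point), c("x", "y", "z")])
}

#' Superior and inferior gyral crest lines around an omega landmark
#'
#' The lateral precentral and postcentral gyri are divided into three parts
#' by lines traced immediately above and below the omega-shaped knob (the
#' hand representation). The lines cross the gyral band from the anterior to
#' the posterior bounding sulcus at a constant inferior-superior level.
#'
#' @param trace_anterior,trace_posterior Sulcal traces (tibbles with
#'   `x`, `y`, `z`, `point`) bounding the gyrus anteriorly and posteriorly.
#' @param omega_apex The apex point of the omega sign (landmark event).
#' @param frame A [hemisphere_frame()].
#' @param half_width Half-height of the middle band in voxels; the lines run
#'   at `apex z + half_width` and `apex z - half_width`.
#' @param prefix `"PRC"` or `"POC"`, used to name the lines
#'   (SPRCL/IPRCL or SPOCL/IPOCL).
#' @return A named list of two `hoa_border` line geometries
#'   (`superior`, `inferior`). The superior line degenerates to the margin
#'   (flagged) when it would leave the gyral band at the top.
#' @export
build_gyral_crest_lines <- function(trace_anterior, trace_posterior, omega_apex,
                                    frame, half_width, prefix = c("PRC", "POC")) {
  prefix <- match.arg(prefix)
  apex <- as_point(omega_apex)
  pa <- trace_points(trace_anterior); pp <- trace_points(trace_posterior)
  x_face <- as.integer(round(stats::median(c(pa[, 1], pp[, 1]))))
  y_at <- function(pts, z) {
    zz <- pts[, 3]
    if (z < min(zz) || z > max(zz)) return(NA_integer_)
    as.integer(round(stats::approx(zz, pts[, 2], xout = z, ties = mean)$y))
  }
  y_ant_apex <- y_at(pa, apex[3]); y_post_apex <- y_at(pp, apex[3])
  if (is.na(y_ant_apex) || is.na(y_post_apex) ||
      apex[2] <= min(y_post_apex, y_ant_apex) || apex[2] >= max(y_post_apex, y_ant_apex)) {
    abort("Omega apex does not lie between the bounding sulcal traces.",
          class = "hoa_geometry_error")
  }
  z_top <- max(c(pa[, 3], pp[, 3])); z_bot <- min(c(pa[, 3], pp[, 3]))
  mk <- function(z_line, nm) {
    degenerate <- FALSE
    if (z_line >= z_top) { z_line <- z_top; degenerate <- TRUE }
    if (z_line <= z_bot) {
      abort("Omega band limit falls below the gyral band.", class = "hoa_geometry_error")
    }
    ys <- sort(c(y_at(pp, z_line), y_at(pa, z_line)))
    wall <- cbind(x_face, seq(ys[1] + 1L, ys[2] - 1L), z_line)
    wall <- wall[in_frame(frame, wall), , drop = FALSE]
    new_border(nm, "surface-line", wall = wall,
               meta = list(z = z_line, degenerate = degenerate))
  }
  sup <- mk(as.integer(round(apex[3] + half_width)), paste0("S", prefix, "L"))
  inf <- mk(as.integer(round(apex[3] - half_width)), paste0("I", prefix, "L"))
  list(superior = sup, inferior = inf)
}

# Dijkstra shortest path over ribbon voxels with 26-connectivity and
# Euclidean step costs; the metric weighting makes the geodesic unique and
# mirror-symmetric on the slab phantoms.
surface_shortest_path <- function(ribbon, frame, p1, p2) {
  dm <- dim(ribbon)
  lin <- function(p) p[1] + (p[2] - 1L) * dm[1] + (p[3] - 1L) * dm[1] * dm[2]
  if (ribbon[lin(p1)] == 0L || ribbon[lin(p2)] == 0L) {
    abort("Parietal line endpoints must lie on the cortical ribbon.",
          class = "hoa_geometry_error")
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  step_cost <- sqrt(rowSums(offs^2))
  dist <- array(Inf, dm); prev <- array(0L, dm)
  dist[lin(p1)] <- 0
  # Bucketed Dijkstra on a fixed cost grid (costs are 1, sqrt2, sqrt3).
  frontier <- lin(p1)
  repeat {
    if (!length(frontier)) break
    d0 <- min(dist[frontier])
    cur <- frontier[dist[frontier] <= d0 + 1e-9]
    frontier <- setdiff(frontier, cur)
    for (ci in cur) {
      p <- c((ci - 1L) %% dm[1] + 1L,
             ((ci - 1L) %/% dm[1]) %% dm[2] + 1L,
             (ci - 1L) %/% (dm[1] * dm[2]) + 1L)
      nb <- sweep(offs, 2, p, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]; sc <- step_cost[ok]
      nl <- nb[, 1] + (nb[, 2] - 1L) * dm[1] + (nb[, 3] - 1L) * dm[1] * dm[2]
      on_rib <- ribbon[nl] > 0L
      nl <- nl[on_rib]; sc <- sc[on_rib]
      nd <- dist[ci] + sc
      upd <- nd < dist[nl] - 1e-9
      if (any(upd)) {
        dist[nl[upd]] <- nd[upd]
        prev[nl[upd]] <- ci
        frontier <- union(frontier, nl[upd])
      }
    }
    if (is.finite(dist[lin(p2)]) && length(frontier) &&
        min(dist[frontier]) >= dist[lin(p2)]) break
  }
  if (!is.finite(dist[lin(p2)])) {
    abort("Parietal line endpoints are not connected on the ribbon.",
          class = "hoa_geometry_error")
  }
  path <- lin(p2); cur <- lin(p2)
  while (cur != lin(p1)) { cur <- prev[cur]; path <- c(cur, path) }
  pts <- cbind((path - 1L) %% dm[1] + 1L,
               ((path - 1L) %/% dm[1]) %% dm[2] + 1L,
               (path - 1L) %/% (dm[1] * dm[2]) + 1L)
  list(points = pts, length = dist[lin(p2)])
}

#' The parietal line (PAL)
#'
#' A surface line connecting the preoccipital notch to the superior terminus
#' of the parieto-occipital sulcus at the hemispheric margin, separating
#' occipital from posterior parietal and temporal cortex. Realized as the
#' metric shortest path over the ribbon's surface-voxel adjacency graph
#' (26-connectivity, Euclidean step costs), a reproducible stand-in for
#' manual tracing on the inflated surface.
#'
#' @param preoccipital_notch,pos_superior_terminus Endpoint voxels.
#' @param frame A [hemisphere_frame()].
#' @param ribbon Ribbon class array.
#' @return An `hoa_border` of kind `"surface-line"`; its `meta$length` is
#'   the geodesic length in voxel units (>= the Euclidean distance).
#' @export
build_parietal_line <- function(preoccipital_notch, pos_superior_terminus,
                                frame, ribbon) {
  p1 <- as.integer(round(as_point(preoccipital_notch)))
  p2 <- as.integer(round(as_point(pos_superior_terminus)))
  if (all(p1 == p2)) {
    abort("Parietal line endpoints coincide (degenerate line).",
          class = "hoa_geometry_error")
  }
  sp <- surface_shortest_path(ribbon, frame, p1, p2)
  pts <- sp$points
  # bridge diagonal steps so the wall is 6-connected and cannot be slipped
  # through by a face-connected fill
  bridged <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    if (sum(abs(a - b)) > 1L) {
      for (ax in 1:3) {
        mid <- a; mid[ax] <- b[ax]
        if (any(mid != a) && any(mid != b) && ribbon[mid[1], mid[2], mid[3]] > 0L) {
          bridged[[length(bridged) + 1L]] <- matrix(mid, ncol = 3)
          break
        }
      }
    }
    bridged[[length(bridged) + 1L]] <- matrix(b, ncol = 3)
  }
  wall_pts <- unique(do.call(rbind, bridged))
  new_border("PAL", "surface-line", wall = wall_pts,
             meta = list(length = sp$length,
                         euclidean = sqrt(sum((p1 - p2)^2))))
}

#' Superior and inferior 45-degree lines of the Sylvian fissure
#'
#' From the posterior terminus of the Sylvian posterior horizontal ramus,
#' rays at +45 and -45 degrees to the local fissure direction are drawn in
#' the parasagittal (posterior-anterior vs inferior-superior) projection.
#' Together with the opercular folds they bound the opercular units near the
#' fissure.
#'
#' @param sylvian_trace Trace of the posterior horizontal ramus.
#' @param frame A [hemisphere_frame()].
#' @return Named list of two `hoa_border` rays (`superior` = S45D,
#'   `inferior` = I45D). Each `meta$angle_deg` records the angle to the
#'   local fissure direction.
#' @export
build_sylvian_opercular_lines <- function(sylvian_trace, frame) {
  pts <- trace_points(sylvian_trace)
  if (nrow(pts) < 2L) {
    abort("Sylvian trace too short to define a direction.",
          class = "hoa_geometry_error")
  }
  i_post <- which.min(pts[, 2])
  term <- pts[i_post, ]
  # Fissure direction from a total least-squares fit of the trace in the
  # parasagittal projection (robust to voxel rounding), oriented anteriorly.
  yz <- pts[, 2:3, drop = FALSE]
  ctr <- sweep(yz, 2, colMeans(yz))
  pc <- svd(ctr)$v[, 1]
  d <- as.numeric(pc)
  if (abs(d[1]) < 1e-6) {
    abort("Sylvian trace is vertical; cannot orient the 45-degree lines.",
          class = "hoa_geometry_error")
  }
  if (d[1] < 0) d <- -d
  d <- d / sqrt(sum(d^2))
  rot <- function(v, theta) c(cos(theta) * v[1] - sin(theta) * v[2],
                              sin(theta) * v[1] + cos(theta) * v[2])
  mk <- function(sgn, nm) {
    # Ray leaves the fissure posteriorly: reflect the anterior-pointing
    # direction, then rotate toward superior (-) or inferior (+).
    dir <- rot(-d, sgn * pi / 4)
    tmax <- max(frame$dim) * 2
    far <- c(term[2] + tmax * dir[1], term[3] + tmax * dir[2])
    st <- staircase2(c(term[2], term[3]), round(far))
    ray <- cbind(term[1], st[, 1], st[, 2])
    ray <- ray[in_frame(frame, ray), , drop = FALSE]
    ang <- acos(abs(sum(dir * d))) * 180 / pi
    new_border(nm, "surface-line", wall = ray,
               meta = list(origin = term, direction = dir, angle_deg = ang))
  }
  list(superior = mk(-1, "S45D"), inferior = mk(+1, "I45D"))
}

#' Calcarine superior and inferior lines (CSL, CIL)
#'
#' Lines flanking the calcarine banks at the sulcal lips, offset from the
#' calcarine trace along the local bank normal. They bound the superior and
#' inferior intracalcarine cortex against supracalcarine cortex and the
#' lingual gyrus.
#'
#' @param calcarine_trace Calcarine sulcus trace (medial surface).
#' @param frame A [hemisphere_frame()].
#' @param bank_width Bank half-height in voxels (the offset distance).
#' @return Named list of two `hoa_border` lines (`superior` = CSL,
#'   `inferior` = CIL); `meta$degenerate` is `TRUE` when `bank_width` is 0
#'   and both lines coincide with the trace (empty calcarine banks).
#' @export
build_calcarine_lines <- function(calcarine_trace, frame, bank_width) {
  if (is.null(calcarine_trace) || nrow(calcarine_trace) == 0L) {
    abort("Calcarine trace is absent.", class = "hoa_geometry_error")
  }
  pts <- trace_points(calcarine_trace)
  n <- nrow(pts)
  mk <- function(sgn, nm) {
    out <- pts
    for (i in seq_len(n)) {
      j0 <- max(1L, i - 1L); j1 <- min(n, i + 1L)
      tang <- c(pts[j1, 2] - pts[j0, 2], pts[j1, 3] - pts[j0, 3])
      if (all(tang == 0)) tang <- c(1, 0)
      tang <- tang / sqrt(sum(tang^2))
      nrm <- c(-tang[2], tang[1])
      if (nrm[2] < 0) nrm <- -nrm        # normal points superior
      out[i, 2] <- round(pts[i, 2] + sgn * bank_width * nrm[1])
      out[i, 3] <- round(pts[i, 3] + sgn * bank_width * nrm[2])
    }
    out <- out[in_frame(frame, out), , drop = FALSE]
    new_border(nm, "surface-line", wall = out,
               meta = list(bank_width = bank_width, degenerate = bank_width == 0))
  }
  list(superior = mk(+1, "CSL"), inferior = mk(-1, "CIL"))
}

#' Midline split of the macaque supratemporal plane
#'
#' The supratemporal plane is divided into anterior and posterior halves at
#' the midpoint of its posterior-anterior extent.
#'
#' @param stp_region Matrix or data frame of voxels belonging to the
#'   supratemporal plane (columns x, y, z).
#' @param frame A [hemisphere_frame()].
#' @return An `hoa_border` coronal cut at `floor((min(y) + max(y)) / 2)`;
#'   `meta$single_slice` flags a one-slice region (posterior half empty).
#' @export
build_stp_midline <- function(stp_region, frame) {
  stp_region <- as.matrix(as.data.frame(stp_region))
  if (nrow(stp_region) == 0L) {
    abort("Supratemporal plane region is empty.", class = "hoa_geometry_error")
  }
  ys <- range(stp_region[, 2])
  new_border("STP_MID", "coronal-plane",
             plane_y = as.integer(floor((ys[1] + ys[2]) / 2)),
             meta = list(extent = ys, single_slice = ys[1] == ys[2]))
}

#' Macaque frontal derived lines: ASL, APL and the premotor plane
#'
#' The superior arcuate line (ASL) extends the superior limb of the arcuate
#' sulcus anteriorly toward the frontal pole, separating the cortex above
#' the principal sulcus into superior and inferior parts. The posterior
#' arcuate line (APL) continues the limb posteriorly, bounding the ventral
#' premotor unit, and the coronal plane through the anterior commissure
#' (CP M) separates the premotor units from the precentral gyrus.
#'
#' @param arcuate_trace Arcuate sulcus trace; its superior limb is the run
#'   of points at the limb's inferior-superior level.
#' @param principal_trace Principal sulcus trace (orientation reference).
#' @param ac_event Anterior-commissure decussation landmark event.
#' @param frame A [hemisphere_frame()].
#' @return Named list of `hoa_border`s: `ASL`, `APL`, `CPM`.
#' @export
build_macaque_frontal_lines <- function(arcuate_trace, principal_trace,
                                        ac_event, frame) {
  pts <- trace_points(arcuate_trace)
  z_top <- max(pts[, 3])
  limb <- pts[pts[, 3] == z_top, , drop = FALSE]
  if (nrow(limb) < 2L) {
    abort("Arcuate sulcus has no identifiable superior limb.",
          class = "hoa_geometry_error")
  }
  tip <- limb[which.max(limb[, 2]), ]
  tail_ <- limb[which.min(limb[, 2]), ]
  d <- c(tip[2] - tail_[2], tip[3] - tail_[3])
  d <- d / sqrt(sum(d^2))
  if (tip[2] >= frame$dim[2]) {
    abort("Arcuate superior limb has no anterior tip inside the frame.",
          class = "hoa_geometry_error")
  }
  ray <- function(from, dir, nm) {
    ts <- seq_len(max(frame$dim) * 2)
    p <- cbind(from[1], round(from[2] + ts * dir[1]), round(from[3] + ts * dir[2]))
    p <- p[in_frame(frame, p), , drop = FALSE]
    new_border(nm, "surface-line", wall = p,
               meta = list(origin = from, direction = dir))
  }
  list(ASL = ray(tip, d, "ASL"),
       APL = ray(tail_, -d, "APL"),
       CPM = build_coronal_plane(ac_event, frame, id = "CP M"))
}

#' Derive the hemispheric margin from ribbon surface classes
#'
#' The hemispheric margin is the dorsal fold where the lateral and medial
#' hemisphere surfaces meet. It is derived as the set of lateral-class
#' ribbon voxels face-adjacent to a medial-class voxel.
#'
#' @param ribbon Ribbon class array (values in
#'   `lateral/medial/ventral/opercular/insular` codes).
#' @param frame A [hemisphere_frame()].
#' @return An `hoa_border` of kind `"margin"`; its `wall` holds the curve
#'   voxels (for inspection; the margin blocks lateral-medial crossings by
#'   class, not by wall occupancy).
#' @export
derive_hemispheric_margin <- function(ribbon, frame) {
  if (!any(ribbon == .hoa_classes["lateral"]) || !any(ribbon == .hoa_classes["medial"])) {
    abort("Ribbon lacks lateral/medial surface annotation.",
          class = "hoa_geometry_error")
  }
  if (!ribbon_connected(ribbon)) {
    abort("Ribbon mask is disconnected.", class = "hoa_geometry_error")
  }
  dm <- dim(ribbon)
  lat <- which(ribbon == .hoa_classes["lateral"])
  curve <- integer()
  for (off in neighbor_offsets(dm)) {
    nb <- lat + off
    ok <- nb >= 1L & nb <= prod(dm)
    hit <- ok
    hit[ok] <- ribbon[nb[ok]] == .hoa_classes["medial"]
    curve <- union(curve, lat[hit])
  }
  pts <- arrayInd(curve, dm)
  new_border("HM", "margin", wall = pts, meta = list(classes = c("lateral", "medial")))
}

neighbor_offsets <- function(dm) {
  list(-1L, 1L, -dm[1], dm[1], -dm[1] * dm[2], dm[1] * dm[2])
}

ribbon_connected <- function(ribbon) {
  dm <- dim(ribbon)
  idx <- which(ribbon > 0L)
  if (!length(idx)) return(FALSE)
  seen <- logical(prod(dm))
  frontier <- idx[1]
  seen[frontier] <- TRUE
  offs <- unlist(neighbor_offsets(dm))
  nmax <- prod(dm)
  while (length(frontier)) {
    nb <- as.vector(outer(frontier, offs, "+"))
    nb <- nb[nb >= 1L & nb <= nmax]
    nb <- nb[!seen[nb] & ribbon[nb] > 0L]
    nb <- unique(nb)
    seen[nb] <- TRUE
    frontier <- nb
  }
  sum(seen) == length(idx)
}
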