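#' @title The rule-application engine
#' @name engine
#' @description
#' The engine turns an ontology plus an annotated hemisphere into a complete
#' disjoint label map. Borders are realized first (planes from landmark
#' events, walls from voxelized sulcal traces and derived lines, fold
#' margins from surface classes); each parcellation unit is then grown as
#' the connected compartment delimited by its own four border slots, in the
#' published table order, over voxels not yet claimed; finally voxels left
#' on border walls are resolved by a deterministic nearest-neighbour
#' tie-break. Left hemispheres are processed in a mirrored canonical
#' orientation so that mirror-image inputs yield mirror-image label maps
#' exactly.
NULL

lin_index <- function(dm, pts) {
  pts[, 1] + (pts[, 2] - 1L) * dm[1] + (pts[, 3] - 1L) * dm[1] * dm[2]
}

get_event <- function(hemi, id) {
  ev <- hemi$events |> filter(.data$landmark == id)
  if (nrow(ev) == 0L) return(NULL)
  ev[1, ]
}

require_event <- function(hemi, id) {
  ev <- get_event(hemi, id)
  if (is.null(ev)) {
    abort(sprintf("Required landmark event absent: %s", id),
          class = "hoa_completeness_error")
  }
  ev
}

get_trace <- function(hemi, id, instance = NULL) {
  tr <- hemi$traces |> filter(.data$sulcus == id)
  if (!is.null(instance)) tr <- tr |> filter(.data$instance == !!instance)
  if (nrow(tr) == 0L) return(NULL)
  tr
}

#' Realize every border symbol used by a species' parcellation rules
#'
#' @param ontology An `hoa_ontology`.
#' @param hemi An `hoa_hemisphere` passing [check_annotation()].
#' @return A named list of `hoa_border` geometries, one per distinct border
#'   symbol (planes, sulci, derived lines, fold margins).
#' @export
realize_borders <- function(ontology, hemi) {
  check_annotation(ontology, hemi)
  frame <- hemi$frame
  dm <- frame$dim
  refs <- ontology$borders |> filter(!is.na(.data$target))
  out <- list()

  # Coronal planes and plane-like landmarks from events.
  plane_ids <- refs |> filter(.data$kind %in% c("plane", "landmark")) |>
    pull("target") |> unique()
  for (pid in plane_ids) {
    if (pid %in% c("Ant end insula", "Post end insula")) {
      ins <- which(hemi$ribbon == .hoa_classes["insular"], arr.ind = TRUE)
      if (nrow(ins) == 0L) {
        abort("No insular-class ribbon voxels; cannot place insula end planes.",
              class = "hoa_geometry_error")
      }
      yv <- if (pid == "Ant end insula") max(ins[, 2]) else min(ins[, 2]) - 1L
      out[[pid]] <- new_border(pid, "coronal-plane", plane_y = as.integer(yv))
    } else {
      ev <- hemi$events |> filter(.data$landmark == pid)
      if (nrow(ev) >= 2L) {
        # Auxiliary plane defined by two anchor points: realized as a
        # voxelized line wall in the parasagittal plane.
        p1 <- c(ev$y[1], ev$z[1]); p2 <- c(ev$y[2], ev$z[2])
        st <- staircase2(p1, p2)
        out[[pid]] <- new_border(pid, "surface-line",
                                 wall = cbind(ev$x[1], st[, 1], st[, 2]))
      } else {
        out[[pid]] <- build_coronal_plane(get_event(hemi, pid), frame, id = pid)
      }
    }
  }

  # Sulcus-terminus planes from qualifiers like "ccs (ant)".
  qual_refs <- refs |> filter(.data$kind == "sulcus", !is.na(.data$qualifier)) |>
    distinct(.data$target, .data$qualifier)
  for (i in seq_len(nrow(qual_refs))) {
    tg <- qual_refs$target[i]; q <- qual_refs$qualifier[i]
    tr <- get_trace(hemi, tg)
    if (is.null(tr)) next
    key <- paste0(tg, " (", q, ")")
    yv <- if (q == "ant") max(tr$y) else min(tr$y) - 1L
    out[[key]] <- new_border(key, "coronal-plane", plane_y = as.integer(yv))
  }

  # Sulcal walls (fold sulci are realized as class margins instead).
  sulcus_ids <- refs |> filter(.data$kind == "sulcus") |> pull("target") |> unique()
  for (sid in setdiff(sulcus_ids, c("cir", "crs"))) {
    if (sid %in% hemi$absent_sulci) {
      out[[sid]] <- new_border(sid, "sulcal-curve", wall = NULL,
                               meta = list(absent = TRUE))
      next
    }
    tr <- get_trace(hemi, sid)
    if (is.null(tr)) {
      abort(sprintf("Required sulcal trace absent and not declared: %s", sid),
            class = "hoa_completeness_error")
    }
    pts <- unique(as.matrix(tr[, c("x", "y", "z")]))
    out[[sid]] <- new_border(sid, "sulcal-curve", wall = pts)
  }
  for (sid in intersect(sulcus_ids, c("cir", "crs"))) {
    out[[sid]] <- new_border(sid, "margin", meta = list(margin = "insula"))
  }

  # Derived lines.
  line_ids <- refs |> filter(.data$kind == "derived-line") |> pull("target") |> unique()
  params <- hemi$params
  calc_id <- if (hemi$species == "human") "calc" else "ccs"
  if (any(c("CSL", "CIL") %in% line_ids)) {
    cl <- build_calcarine_lines(get_trace(hemi, calc_id), frame,
                                params$calc_bank_width %||% 2)
    out[["CSL"]] <- cl$superior
    out[["CIL"]] <- cl$inferior
  }
  if ("HM" %in% line_ids) {
    out[["HM"]] <- new_border("HM", "margin", meta = list(margin = "hm"))
  }
  if (any(c("S45D", "I45D") %in% line_ids)) {
    rays <- build_sylvian_opercular_lines(get_trace(hemi, "phr"), frame)
    out[["S45D"]] <- new_border("S45D", "margin", wall = rays$superior$wall,
                                meta = c(rays$superior$meta, margin = "s45d"))
    out[["I45D"]] <- new_border("I45D", "margin", wall = rays$inferior$wall,
                                meta = c(rays$inferior$meta, margin = "i45d"))
  }
  if (any(c("SPRCL", "IPRCL") %in% line_ids)) {
    gl <- build_gyral_crest_lines(get_trace(hemi, "prs"), get_trace(hemi, "ce"),
                                  require_event(hemi, .aux_events[["omega_prc"]]),
                                  frame, params$omega_half_width %||% 5, "PRC")
    out[["SPRCL"]] <- gl$superior; out[["IPRCL"]] <- gl$inferior
  }
  if (any(c("SPOCL", "IPOCL") %in% line_ids)) {
    gl <- build_gyral_crest_lines(get_trace(hemi, "ce"), get_trace(hemi, "pcs"),
                                  require_event(hemi, .aux_events[["omega_poc"]]),
                                  frame, params$omega_half_width %||% 5, "POC")
    out[["SPOCL"]] <- gl$superior; out[["IPOCL"]] <- gl$inferior
  }
  if ("PAL" %in% line_ids) {
    out[["PAL"]] <- build_parietal_line(require_event(hemi, .aux_events[["pon"]]),
                                        require_event(hemi, .aux_events[["po_sup"]]),
                                        frame, hemi$ribbon)
  }
  if (any(c("ASL", "APL") %in% line_ids)) {
    ml <- build_macaque_frontal_lines(get_trace(hemi, "arc"), get_trace(hemi, "prs"),
                                      require_event(hemi, "CP M"), frame)
    out[["ASL"]] <- ml$ASL; out[["APL"]] <- ml$APL
  }
  if ("STP_MID" %in% line_ids) {
    # the supratemporal plane is the inferior of the two opercular sheets
    op <- which(hemi$ribbon == .hoa_classes["opercular"], arr.ind = TRUE)
    stp <- op[op[, 3] < mean(range(op[, 3])), , drop = FALSE]
    out[["STP_MID"]] <- build_stp_midline(stp, frame)
  }
  out
}

#' Apply the conditional lateral-orbital merge rule
#'
#' When the lateral orbital sulcus is present as a single sulcus, the
#' lateral fronto-orbital unit and the pars opercularis unit it is normally
#' divided from are combined into one unit (`FOCL/F3o`). When the sulcus is
#' duplicated the two units stay separate, divided on the duplicated
#' sulcus. Macaque input is returned unchanged.
#'
#' @param ontology An `hoa_ontology`.
#' @param hemi An `hoa_hemisphere`.
#' @return An effective `hoa_ontology` (possibly with the merged unit).
#' @export
apply_focl_f3o_merge <- function(ontology, hemi) {
  if (ontology$species != "human") return(ontology)
  lorb <- get_trace(hemi, "lorb")
  if (is.null(lorb) && !("lorb" %in% hemi$absent_sulci)) {
    abort("No lateral orbital sulcus trace (lorb).", class = "hoa_completeness_error")
  }
  n_inst <- if (is.null(lorb)) 0L else dplyr::n_distinct(lorb$instance)
  if (n_inst >= 2L) return(ontology)

  merged_id <- "FOCL/F3o"
  pair <- c("FOCL", "F3o")
  units <- ontology$units
  # keep the later of the two source rows so tie-breaks at borders with
  # unmerged neighbours are unchanged by the merge
  keep_row <- max(units$row[units$id %in% pair])
  merged <- units[units$id == "F3o", ]
  merged$id <- merged_id
  merged$name <- "Frontal orbital cortex, lateral / pars opercularis (combined)"
  merged$merge_partner <- NA_character_
  merged$row <- keep_row
  units <- bind_rows(units[!(units$id %in% pair), ], merged) |> arrange(.data$row)

  borders <- ontology$borders |> filter(!(.data$pu %in% pair))
  mb <- ontology$borders |> filter(.data$pu %in% pair, .data$target != "lorb" | is.na(.data$target)) |>
    mutate(pu = merged_id) |>
    distinct(.data$slot, .data$kind, .data$target, .data$qualifier, .keep_all = TRUE)
  borders <- bind_rows(borders, mb)

  surfaces <- ontology$surfaces |> filter(!(.data$pu %in% pair)) |>
    bind_rows(tibble(pu = merged_id, classes = "lateral;ventral"))

  out <- ontology
  out$units <- units
  out$borders <- borders
  out$surfaces <- surfaces
  out
}

# Per-unit blocking specification extracted from realized borders.
unit_blocking <- function(ontology, pu_id, borders, dm) {
  refs <- ontology$borders |>
    filter(.data$pu == pu_id, !is.na(.data$target))
  planes <- integer(); walls <- integer(); margins <- character()
  has_bank_line <- any(refs$target %in% c("CSL", "CIL"))
  for (i in seq_len(nrow(refs))) {
    tg <- refs$target[i]; q <- refs$qualifier[i]
    key <- if (!is.na(q)) paste0(tg, " (", q, ")") else tg
    b <- borders[[key]] %||% borders[[tg]]
    if (is.null(b)) next
    if (!is.null(b$plane_y)) planes <- c(planes, b$plane_y)
    if (!is.null(b$wall)) walls <- c(walls, lin_index(dm, b$wall))
    if (b$kind == "margin") margins <- c(margins, b$meta$margin %||% tolower(b$id))
    # A unit bounded by a sulcus with bank lines, but not itself a bank,
    # is kept out of the whole sulcal band.
    if (b$kind == "sulcal-curve" && b$id %in% c("calc", "ccs") && !has_bank_line) {
      for (ln in c("CSL", "CIL")) {
        if (!is.null(borders[[ln]]) && !is.null(borders[[ln]]$wall)) {
          walls <- c(walls, lin_index(dm, borders[[ln]]$wall))
        }
      }
    }
  }
  list(planes = unique(planes), walls = unique(walls), margins = unique(margins))
}

# Vectorized constrained BFS from a seed set over an allowed mask.
grow_component <- function(seed, allowed, dm, block) {
  visited <- logical(length(allowed))
  visited[seed] <- TRUE
  frontier <- seed
  nxy <- dm[1] * dm[2]
  offs <- c(-1L, 1L, -dm[1], dm[1], -nxy, nxy)
  while (length(frontier)) {
    nxt <- integer()
    for (k in seq_along(offs)) {
      nb <- frontier + offs[k]
      ok <- nb >= 1L & nb <= length(allowed)
      nb <- nb[ok]; fr <- frontier[ok]
      keep <- allowed[nb] & !visited[nb]
      nb <- nb[keep]; fr <- fr[keep]
      if (!length(nb)) next
      pass <- block(fr, nb, k)
      nb <- nb[pass]
      if (length(nb)) {
        visited[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
    }
    frontier <- unique(nxt)
  }
  which(visited)
}

make_block_fn <- function(dm, planes, margins, class_arr) {
  nxy <- dm[1] * dm[2]
  y_of <- function(idx) ((idx - 1L) %/% dm[1]) %% dm[2] + 1L
  z_of <- function(idx) (idx - 1L) %/% nxy + 1L
  lat <- .hoa_classes[["lateral"]]; med <- .hoa_classes[["medial"]]
  op <- .hoa_classes[["opercular"]]; ins <- .hoa_classes[["insular"]]
  function(from, to, k) {
    pass <- rep(TRUE, length(from))
    if (length(planes) && k %in% 3:4) {
      yf <- y_of(from); yt <- y_of(to)
      ymin <- pmin(yf, yt)
      pass <- pass & !(ymin %in% planes)
    }
    if (length(margins)) {
      cf <- class_arr[from]; ct <- class_arr[to]
      if ("hm" %in% margins) {
        pass <- pass & !((cf == lat & ct == med) | (cf == med & ct == lat))
      }
      if ("insula" %in% margins) {
        pass <- pass & !((cf == ins) != (ct == ins))
      }
      latop <- (cf == lat & ct == op) | (cf == op & ct == lat)
      if (any(latop) && any(c("s45d", "i45d") %in% margins)) {
        zf <- z_of(from); zt <- z_of(to)
        zlat <- ifelse(class_arr[from] == lat, zf, zt)
        zop <- ifelse(class_arr[from] == op, zf, zt)
        if ("s45d" %in% margins) pass <- pass & !(latop & zlat > zop)
        if ("i45d" %in% margins) pass <- pass & !(latop & zlat < zop)
        if (all(c("s45d", "i45d") %in% margins) || any(latop & zlat == zop)) {
          pass <- pass & !(latop & zlat == zop)
        }
      }
    }
    pass
  }
}

# Does a component touch a given realized border, on the side implied by
# the border's slot? A unit lies posterior of its anterior border and
# anterior of its posterior border; for the medial-inferior and
# lateral-superior slots (whose geometric sense varies across the cortex)
# any adjacency counts.
comp_touches <- function(comp_mask, comp_idx, border, dm, margin_sets, slot,
                         z_slots = FALSE) {
  y_of <- function(idx) ((idx - 1L) %/% dm[1]) %% dm[2] + 1L
  z_of <- function(idx) (idx - 1L) %/% (dm[1] * dm[2]) + 1L
  if (!is.null(border$plane_y)) {
    y <- y_of(comp_idx)
    return(switch(slot,
                  anterior = any(y == border$plane_y),
                  posterior = any(y == border$plane_y + 1L),
                  any(y == border$plane_y | y == border$plane_y + 1L)))
  }
  near_set <- function(ms) {
    if (is.null(ms) || !length(ms)) return(FALSE)
    if (any(comp_mask[ms])) return(TRUE)
    nxy <- dm[1] * dm[2]
    for (off in c(-1L, 1L, -dm[1], dm[1], -nxy, nxy)) {
      nb <- ms + off
      nb <- nb[nb >= 1L & nb <= length(comp_mask)]
      if (any(comp_mask[nb])) return(TRUE)
    }
    FALSE
  }
  if (border$kind == "margin" && !is.null(border$meta$margin)) {
    ms <- margin_sets[[border$meta$margin]]
    if (near_set(ms)) return(TRUE)
    if (identical(border$meta$margin, "hm")) {
      # An opercular sheet bounded by the hemispheric margin abuts the
      # lateral cortex at its Sylvian lip: superior sheet for a
      # lateral-superior slot, inferior sheet for a medial-inferior slot.
      lip <- switch(slot, lateral_superior = margin_sets$op_upper,
                    medial_inferior = margin_sets$op_lower, NULL)
      if (!is.null(lip) && near_set(lip)) return(TRUE)
    }
    if (is.null(border$wall)) return(FALSE)
  }
  if (!is.null(border$wall)) {
    w <- lin_index(dm, border$wall)
    nxy <- dm[1] * dm[2]
    wy <- y_of(w)
    wz <- z_of(w)
    for (off in c(-1L, 1L, -dm[1], dm[1], -nxy, nxy)) {
      nb <- w + off
      ok <- nb >= 1L & nb <= length(comp_mask)
      hit <- ok & comp_mask[pmax(pmin(nb, length(comp_mask)), 1L)]
      if (!any(hit)) next
      if (slot == "anterior") {
        if (any(y_of(nb[hit]) < wy[hit])) return(TRUE)
      } else if (slot == "posterior") {
        if (any(y_of(nb[hit]) > wy[hit])) return(TRUE)
      } else if (z_slots && slot == "lateral_superior") {
        # printed Superior column: unit below the wall (or beside it, for
        # walls running on the ventral sheet)
        if (any(z_of(nb[hit]) < wz[hit] | z_of(nb[hit]) == wz[hit] & y_of(nb[hit]) == wy[hit])) return(TRUE)
      } else if (z_slots && slot == "medial_inferior") {
        if (any(z_of(nb[hit]) > wz[hit] | z_of(nb[hit]) == wz[hit] & y_of(nb[hit]) == wy[hit])) return(TRUE)
      } else {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Effective anterior/posterior bounds of a unit from its plane cuts; used to
# reunite compartments that the unit's own interior cuts split.
unit_plane_interval <- function(refs, borders) {
  cut_of <- function(i) {
    key <- if (!is.na(refs$qualifier[i]))
      paste0(refs$target[i], " (", refs$qualifier[i], ")") else refs$target[i]
    b <- borders[[key]] %||% borders[[refs$target[i]]]
    if (is.null(b) || is.null(b$plane_y)) NA_integer_ else b$plane_y
  }
  cuts <- vapply(seq_len(nrow(refs)), cut_of, integer(1))
  ant <- cuts[refs$slot == "anterior" & !is.na(cuts)]
  post <- cuts[refs$slot == "posterior" & !is.na(cuts)]
  lo <- if (length(post)) min(post) else -Inf
  hi <- if (length(ant)) max(ant) else Inf
  inside <- unique(cuts[!is.na(cuts) & cuts >= lo & cuts < hi])
  list(lo = lo, hi = hi, inside = inside)
}

# TRUE when `piece` is y-adjacent to `claim` straddling the plane cut `c`.
adjacent_across_cut <- function(claim, piece, c, dm) {
  y_of <- function(idx) ((idx - 1L) %/% dm[1]) %% dm[2] + 1L
  a <- claim[y_of(claim) == c]; b <- piece[y_of(piece) == c + 1L]
  if (length(a) && length(b) && length(intersect(a + dm[1], b))) return(TRUE)
  a <- claim[y_of(claim) == c + 1L]; b <- piece[y_of(piece) == c]
  length(a) && length(b) && length(intersect(a - dm[1], b)) > 0L
}

# TRUE when `piece` touches `claim` through a margin-type fold (e.g. the
# hemispheric margin between lateral- and medial-class voxels).
adjacent_across_margin <- function(claim, piece, pair, class_arr, dm) {
  nxy <- dm[1] * dm[2]
  offs <- c(-1L, 1L, -dm[1], dm[1], -nxy, nxy)
  a <- claim[class_arr[claim] %in% pair]
  b <- piece[class_arr[piece] %in% pair]
  if (!length(a) || !length(b)) return(FALSE)
  bset <- logical(length(class_arr)); bset[b] <- TRUE
  for (off in offs) {
    nb <- a + off
    ok <- nb >= 1L & nb <= length(class_arr)
    if (any(bset[nb[ok]] & class_arr[nb[ok]] != class_arr[a[ok]])) return(TRUE)
  }
  FALSE
}

precompute_margin_sets <- function(class_arr, dm) {
  lat <- .hoa_classes[["lateral"]]; med <- .hoa_classes[["medial"]]
  op <- .hoa_classes[["opercular"]]; ins <- .hoa_classes[["insular"]]
  nxy <- dm[1] * dm[2]
  offs <- c(-1L, 1L, -dm[1], dm[1], -nxy, nxy)
  z_of <- function(idx) (idx - 1L) %/% nxy + 1L
  adj_pairs <- function(code_a, code_b, zrel = NULL) {
    ia <- which(class_arr == code_a)
    hitset <- integer()
    for (off in offs) {
      nb <- ia + off
      ok <- nb >= 1L & nb <= length(class_arr)
      sel <- ok
      sel[ok] <- class_arr[nb[ok]] == code_b
      if (!is.null(zrel) && any(sel)) {
        za <- z_of(ia[sel]); zb <- z_of(nb[sel])
        keep <- if (zrel == "above") za > zb else za < zb
        idx2 <- which(sel); sel[idx2[!keep]] <- FALSE
      }
      hitset <- c(hitset, ia[sel], nb[sel & ok])
    }
    unique(hitset)
  }
  list(hm = adj_pairs(lat, med),
       insula = adj_pairs(ins, lat) |> union(adj_pairs(ins, op)) |>
         union(adj_pairs(ins, med)) |> union(adj_pairs(ins, .hoa_classes[["ventral"]])),
       s45d = adj_pairs(lat, op, zrel = "above"),
       i45d = adj_pairs(lat, op, zrel = "below"),
       op_upper = adj_pairs(op, lat, zrel = "below"),
       op_lower = adj_pairs(op, lat, zrel = "above"))
}

#' Assign parcellation-unit labels to every ribbon voxel
#'
#' Runs the full rule set: realizes borders, applies the conditional
#' lateral-orbital merge, grows each unit's compartment, and resolves
#' residual border-wall voxels by a deterministic neighbour-majority
#' tie-break (ties broken by table order). The result is a partition of the
#' ribbon: every voxel gets exactly one unit label.
#'
#' @param ontology An `hoa_ontology`.
#' @param hemi An `hoa_hemisphere`.
#' @param borders Optional precomputed [realize_borders()] result (for the
#'   effective, merged ontology).
#' @return An `hoa_labelmap`.
#' @export
assign_labels <- function(ontology, hemi, borders = NULL, tiebreak = TRUE) {
  stopifnot(inherits(ontology, "hoa_ontology"), inherits(hemi, "hoa_hemisphere"))
  if (hemi$frame$side == "left") {
    lm <- assign_labels(ontology, mirror_x(hemi), borders = NULL)
    return(mirror_labelmap(lm))
  }
  eff <- apply_focl_f3o_merge(ontology, hemi)
  if (is.null(borders)) borders <- realize_borders(eff, hemi)
  frame <- hemi$frame
  dm <- frame$dim
  class_arr <- as.integer(hemi$ribbon)
  rib <- class_arr > 0L
  labels <- integer(length(class_arr))
  margin_sets <- precompute_margin_sets(class_arr, dm)

  units <- eff$units |> arrange(.data$row)
  surf <- setNames(eff$surfaces$classes, eff$surfaces$pu)
  empty_units <- character()
  codes <- seq_len(nrow(units))

  for (ui in codes) {
    pid <- units$id[ui]
    classes <- strsplit(surf[[pid]] %||% paste(names(.hoa_classes), collapse = ";"),
                        ";")[[1]]
    class_codes <- .hoa_classes[classes]
    blk <- unit_blocking(eff, pid, borders, dm)
    # A calcarine bank unit whose bank lines coincide with the fundus trace
    # (zero bank width) is legitimately empty.
    refs0 <- eff$borders |> filter(.data$pu == pid, !is.na(.data$target))
    if (any(refs0$target %in% c("calc", "ccs")) &&
        any(refs0$target %in% c("CIL", "CSL"))) {
      bank_line <- borders[["CIL"]] %||% borders[["CSL"]]
      if (!is.null(bank_line) && isTRUE(bank_line$meta$degenerate)) {
        empty_units <- c(empty_units, pid)
        next
      }
    }
    allowed <- rib & labels == 0L & (class_arr %in% class_codes)
    if (length(blk$walls)) allowed[blk$walls] <- FALSE
    if (!any(allowed)) { empty_units <- c(empty_units, pid); next }
    block_fn <- make_block_fn(dm, blk$planes, blk$margins, class_arr)

    # Enumerate compartments; keep the one delimited by the most of the
    # unit's own borders (ties: the smaller compartment), then reunite any
    # sibling compartments that only the unit's own interior plane cuts
    # split off (e.g. a unit listing several planes in one slot).
    refs <- eff$borders |> filter(.data$pu == pid, !is.na(.data$target))
    interval <- unit_plane_interval(refs, borders)
    z_slots <- eff$species == "macaque"
    has_bank <- any(refs$target %in% c("CSL", "CIL"))
    score_comp <- function(comp) {
      comp_mask <- logical(length(class_arr)); comp_mask[comp] <- TRUE
      score <- 0L
      nonplane <- FALSE
      hit <- character()
      for (i in seq_len(nrow(refs))) {
        key <- if (!is.na(refs$qualifier[i]))
          paste0(refs$target[i], " (", refs$qualifier[i], ")") else refs$target[i]
        b <- borders[[key]] %||% borders[[refs$target[i]]]
        if (is.null(b) || key %in% hit) next
        touched <- comp_touches(comp_mask, comp, b, dm, margin_sets,
                                refs$slot[i], z_slots)
        if (!touched && key %in% c("calc", "ccs") && !has_bank) {
          # the whole sulcal band stands for the calcarine complex
          for (ln in c("CSL", "CIL")) {
            bb <- borders[[ln]]
            if (!is.null(bb) &&
                comp_touches(comp_mask, comp, bb, dm, margin_sets, refs$slot[i], z_slots)) {
              touched <- TRUE; break
            }
          }
        }
        if (touched) {
          hit <- c(hit, key)
          score <- score + 1L
          if (is.null(b$plane_y)) nonplane <- TRUE
        }
      }
      list(score = score, nonplane = nonplane)
    }
    comps <- list(); scores <- integer(); nonplane <- logical()
    claimed_frac <- numeric()
    nxy <- dm[1] * dm[2]
    remaining <- allowed
    while (any(remaining)) {
      comp <- grow_component(which.max(remaining), remaining, dm, block_fn)
      remaining[comp] <- FALSE
      comps[[length(comps) + 1L]] <- comp
      sc <- score_comp(comp)
      scores <- c(scores, sc$score)
      nonplane <- c(nonplane, sc$nonplane)
      # Leftover slivers along already-decided borders are almost entirely
      # adjacent to claimed territory; genuine compartments are not.
      near_claimed <- logical(length(comp))
      for (off in c(-1L, 1L, -dm[1], dm[1], -nxy, nxy)) {
        nb <- comp + off
        ok <- nb >= 1L & nb <= length(labels)
        near_claimed[ok] <- near_claimed[ok] | labels[nb[ok]] > 0L
      }
      claimed_frac <- c(claimed_frac, mean(near_claimed))
    }
    if (identical(getOption("hoacompare.debug_pu"), pid)) {
      for (j in seq_along(comps)) {
        ai <- arrayInd(comps[[j]][1:min(3, length(comps[[j]]))], dm)
        message(sprintf("comp %d: size %d score %d nonplane %s at (%s)", j,
                        length(comps[[j]]), scores[j], nonplane[j],
                        paste(apply(ai, 1, paste, collapse=","), collapse=" | ")))
      }
    }
    if (!length(comps) || max(scores) <= 0L) { empty_units <- c(empty_units, pid); next }
    sizes <- lengths(comps)
    best_i <- order(-scores, claimed_frac, sizes)[1]
    claim <- comps[[best_i]]
    # Margins listed in two or more slots mean the unit wraps that fold
    # (e.g. a pole unit bounded by the hemispheric margin on three sides).
    wrap_margins <- refs |> filter(.data$kind == "derived-line" | .data$kind == "sulcus") |>
      filter(.data$target %in% c("HM", "cir", "crs")) |>
      distinct(.data$target, .data$slot) |> count(.data$target) |> filter(.data$n >= 2L)
    margin_pairs <- list(HM = .hoa_classes[c("lateral", "medial")],
                         cir = .hoa_classes[c("insular", "opercular")],
                         crs = .hoa_classes[c("insular", "opercular")])
    taken <- seq_along(comps) == best_i
    y_of <- function(idx) ((idx - 1L) %/% dm[1]) %% dm[2] + 1L
    repeat {
      added <- FALSE
      for (j in seq_along(comps)) {
        if (taken[j] || scores[j] < 2L || !nonplane[j]) next
        yy <- y_of(comps[[j]])
        in_interval <- all(yy > interval$lo & yy <= interval$hi)
        join <- FALSE
        if (in_interval && length(interval$inside)) {
          join <- any(vapply(interval$inside, function(cc)
            adjacent_across_cut(claim, comps[[j]], cc, dm), logical(1)))
        }
        if (!join && nrow(wrap_margins)) {
          join <- any(vapply(wrap_margins$target, function(mm)
            adjacent_across_margin(claim, comps[[j]], margin_pairs[[mm]],
                                   class_arr, dm), logical(1)))
        }
        if (join) {
          claim <- c(claim, comps[[j]])
          taken[j] <- TRUE
          added <- TRUE
        }
      }
      if (!added) break
    }
    labels[claim] <- ui
  }

  labels <- apply_lorb_strip_rule(eff, hemi, labels, dm, units)
  if (tiebreak) labels <- resolve_unclaimed(labels, rib, dm, units$row)

  lut <- tibble(code = codes, pu = units$id, name = units$name,
                lobe = units$lobe, side = frame$side)
  new_labelmap(frame, array(labels, dm), lut, hemi$species,
               empty_units = setdiff(empty_units, c()),
               provenance = list(borders = names(borders),
                                 merged = "FOCL/F3o" %in% units$id))
}

# The printed footnote rule for the duplicated lateral orbital sulcus: the
# orbital strip lateral to the outermost lorb instance belongs to the pars
# opercularis unit (or to the combined unit when the sulcus is single).
apply_lorb_strip_rule <- function(eff, hemi, labels, dm, units) {
  if (hemi$species != "human") return(labels)
  lorb <- get_trace(hemi, "lorb")
  if (is.null(lorb)) return(labels)
  owner <- if ("FOCL/F3o" %in% units$id) "FOCL/F3o" else "F3o"
  code <- which(units$id == owner)
  if (!length(code)) return(labels)
  inst <- lorb |> group_by(.data$instance) |> summarise(mx = mean(.data$x))
  outer_inst <- inst$instance[which.max(inst$mx)]
  wall <- lin_index(dm, as.matrix(lorb |> filter(.data$instance == outer_inst) |>
                                    select("x", "y", "z")))
  vent <- .hoa_classes[["ventral"]]
  class_arr <- as.integer(hemi$ribbon)
  wx <- max(((wall - 1L) %% dm[1]) + 1L)
  # Only the orbital strip strictly lateral of the outermost instance is in
  # play; wall voxels themselves stay with the generic tie-break.
  x_of <- function(idx) ((idx - 1L) %% dm[1]) + 1L
  unclaimed <- class_arr == vent & labels == 0L &
    x_of(seq_along(labels)) > wx
  seeds <- integer()
  nxy <- dm[1] * dm[2]
  for (off in c(-1L, 1L, -dm[1], dm[1], -nxy, nxy)) {
    nb <- wall + off
    nb <- nb[nb >= 1L & nb <= length(labels)]
    nb <- nb[unclaimed[nb] & (((nb - 1L) %% dm[1]) + 1L) > wx]
    seeds <- union(seeds, nb)
  }
  if (!length(seeds)) return(labels)
  comp <- grow_component(seeds, unclaimed, dm, function(from, to, k) rep(TRUE, length(from)))
  labels[comp] <- code
  labels
}

# Iterative neighbour-majority assignment of voxels left on border walls;
# ties broken by the earlier unit in the source table (stable under the
# conditional merge, which keeps original row numbers).
resolve_unclaimed <- function(labels, rib, dm, rows) {
  nxy <- dm[1] * dm[2]
  offs <- c(-1L, 1L, -dm[1], dm[1], -nxy, nxy)
  repeat {
    todo <- which(rib & labels == 0L)
    if (!length(todo)) break
    votes <- matrix(0L, nrow = length(todo), ncol = length(offs))
    for (k in seq_along(offs)) {
      nb <- todo + offs[k]
      ok <- nb >= 1L & nb <= length(labels)
      v <- integer(length(todo))
      v[ok] <- labels[nb[ok]]
      votes[, k] <- v
    }
    pick <- apply(votes, 1, function(v) {
      v <- v[v > 0L]
      if (!length(v)) return(0L)
      tb <- table(v)
      cand <- as.integer(names(tb)[tb == max(tb)])
      cand[which.min(rows[cand])]
    })
    if (!any(pick > 0L)) break  # isolated unclaimed voxels (shouldn't happen)
    labels[todo[pick > 0L]] <- pick[pick > 0L]
  }
  labels
}
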