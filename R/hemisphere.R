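#' Assemble an annotated hemisphere
#'
#' An annotated hemisphere bundles everything the labeling engine needs: the
#' cortical-ribbon mask with surface-class tags (lateral, medial, ventral,
#' opercular, insular), the labeled sulcal traces, the landmark events that
#' anchor the coronal limiting planes, and a small set of numeric
#' parameters for derived-line construction (calcarine bank width, omega
#' band half-width).
#'
#' @param frame A [hemisphere_frame()].
#' @param ribbon Integer array of `frame$dim` with surface-class codes
#'   (0 = background; see `hoa_surface_classes()`).
#' @param traces Tibble with columns `sulcus`, `instance`, `point`,
#'   `x`, `y`, `z` (voxel coordinates).
#' @param events Tibble with columns `landmark`, `x`, `y`, `z`.
#' @param species `"human"` or `"macaque"`.
#' @param params Named list of derived-line parameters
#'   (`calc_bank_width`, `omega_half_width`).
#' @param absent_sulci Character vector of sulci declared absent in this
#'   hemisphere (anatomical variability); affected borders are skipped with
#'   a warning at labeling time.
#' @return An object of class `hoa_hemisphere`.
#' @export
annotated_hemisphere <- function(frame, ribbon, traces, events,
                                 species = c("human", "macaque"),
                                 params = list(), absent_sulci = character()) {
  species <- match.arg(species)
  stopifnot(inherits(frame, "hoa_frame"))
  if (!identical(dim(ribbon), as.integer(frame$dim))) {
    abort("Ribbon dimensions do not match the frame.", class = "hoa_input_error")
  }
  traces <- as_tibble(traces)
  events <- as_tibble(events)
  need_t <- c("sulcus", "instance", "point", "x", "y", "z")
  if (!all(need_t %in% names(traces))) {
    abort(sprintf("Traces must have columns %s.", paste(need_t, collapse = ", ")),
          class = "hoa_input_error")
  }
  if (!all(c("landmark", "x", "y", "z") %in% names(events))) {
    abort("Events must have columns landmark, x, y, z.", class = "hoa_input_error")
  }
  pts <- as.matrix(traces[, c("x", "y", "z")])
  if (nrow(pts) && any(!in_frame(frame, pts))) {
    abort("Sulcal trace points fall outside the frame.", class = "hoa_input_error")
  }
  npts <- traces |> count(.data$sulcus, .data$instance)
  if (any(npts$n < 2L)) {
    bad <- npts$sulcus[npts$n < 2L][1]
    abort(sprintf("Trace for '%s' has fewer than 2 points.", bad),
          class = "hoa_input_error")
  }
  if (any(traces$instance < 1L)) {
    abort("Trace instance indices must be >= 1.", class = "hoa_input_error")
  }
  structure(list(frame = frame, ribbon = ribbon, traces = traces,
                 events = events, species = species, params = params,
                 absent_sulci = absent_sulci),
            class = "hoa_hemisphere")
}

#' Surface class codes used in ribbon masks
#' @return Named integer vector mapping class names to ribbon codes.
#' @export
hoa_surface_classes <- function() .hoa_classes

#' @export
print.hoa_hemisphere <- function(x, ...) {
  cat(sprintf("<hoa_hemisphere> %s, %s side: %d ribbon voxels, %d traces, %d events\n",
              x$species, x$frame$side, sum(x$ribbon > 0L),
              nrow(dplyr::distinct(x$traces, .data$sulcus, .data$instance)),
              nrow(x$events)))
  invisible(x)
}

# Auxiliary landmark-event ids beyond the printed plane tables: anchors for
# derived lines that the tracing protocol supplies by inspection.
.aux_events <- c(omega_prc = "omega precentral apex",
                 omega_poc = "omega postcentral apex",
                 pon = "preoccipital notch",
                 po_sup = "parieto-occipital superior terminus")

#' Check an annotated hemisphere for completeness against an ontology
#'
#' Verifies that every sulcus and landmark referenced by the species'
#' border rules has a trace/event or is declared absent, and that duplicated
#' traces are only given for sulci allowed to duplicate.
#'
#' @param ontology An `hoa_ontology`.
#' @param hemi An `hoa_hemisphere`.
#' @return Invisibly, a list with `missing_sulci`, `missing_events`; throws
#'   a completeness error when required annotation is absent.
#' @export
check_annotation <- function(ontology, hemi) {
  stopifnot(inherits(ontology, "hoa_ontology"), inherits(hemi, "hoa_hemisphere"))
  if (!identical(ontology$species, hemi$species)) {
    abort("Ontology and hemisphere species differ.", class = "hoa_input_error")
  }
  # Sulci realized from surface-class folds rather than traces.
  fold_sulci <- c("cir", "crs")
  refs <- ontology$borders |> filter(.data$kind == "sulcus", !is.na(.data$target))
  required <- setdiff(unique(refs$target), fold_sulci)
  have <- unique(hemi$traces$sulcus)
  missing_sulci <- setdiff(required, c(have, hemi$absent_sulci))

  plane_refs <- ontology$borders |>
    filter(.data$kind %in% c("plane", "landmark"), !is.na(.data$target)) |>
    pull("target") |> unique()
  implicit <- c("Ant end insula", "Post end insula")
  missing_events <- setdiff(setdiff(plane_refs, implicit), hemi$events$landmark)

  dup <- hemi$traces |> distinct(.data$sulcus, .data$instance) |>
    count(.data$sulcus) |> filter(.data$n > 1L)
  dup_ok <- ontology$sulci$abbrev[ontology$sulci$may_duplicate]
  bad_dup <- setdiff(dup$sulcus, dup_ok)
  if (length(bad_dup)) {
    abort(sprintf("Sulcus '%s' is traced more than once but is not listed as one that may exist as two or more sulci.",
                  bad_dup[1]), class = "hoa_input_error")
  }
  if (length(missing_sulci) || length(missing_events)) {
    abort(sprintf("Annotation incomplete. Missing traces: %s. Missing events: %s.",
                  paste(missing_sulci, collapse = ", "),
                  paste(missing_events, collapse = ", ")),
          class = "hoa_completeness_error")
  }
  invisible(list(missing_sulci = missing_sulci, missing_events = missing_events))
}

mirror_x <- function(hemi) {
  dmx <- hemi$frame$dim[1]
  frame <- hemi$frame
  frame$side <- if (frame$side == "right") "left" else "right"
  rib <- hemi$ribbon[dmx:1, , , drop = FALSE]
  traces <- hemi$traces |> mutate(x = dmx + 1 - .data$x)
  events <- hemi$events |> mutate(x = dmx + 1 - .data$x)
  annotated_hemisphere(frame, rib, traces, events, hemi$species,
                       hemi$params, hemi$absent_sulci)
}
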