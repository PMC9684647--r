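#' @title Regional volumetry
#' @name morphometry
#' @description
#' Regional volumes follow the voxel-counting convention of the atlas: the
#' number of voxels carrying a unit's label is its volume, converted to
#' cubic centimetres with the frame's voxel size. Internal arithmetic stays
#' in integer voxel counts; cm3 values are a derived column. The packaged
#' single-subject reference tables can be joined for descriptive
#' comparison (they derive from one real MRI session and are not
#' reproducible from phantoms).
NULL

#' Compute per-unit volumes from a label map
#'
#' @param labelmap An `hoa_labelmap`.
#' @return A tibble with one row per parcellation unit: `pu`, `name`,
#'   `lobe`, `hemisphere`, `voxels`, `volume_cm3` (voxel count times voxel
#'   volume; empty units keep a 0.00 row). The frame's voxel volume (mm3)
#'   is attached as attribute `voxel_volume_mm3`.
#' @examples
#' ph <- generate_phantom(phantom_spec("macaque"))
#' head(compute_volumes(ph$truth))
#' @export
compute_volumes <- function(labelmap) {
  stopifnot(inherits(labelmap, "hoa_labelmap"))
  if (any(!(labelmap$labels %in% c(0L, labelmap$lut$code)))) {
    abort("Label map contains codes absent from its lookup table.",
          class = "hoa_input_error")
  }
  vv <- prod(labelmap$frame$voxel_mm)
  out <- tidy(labelmap) |>
    mutate(hemisphere = labelmap$frame$side,
           volume_cm3 = .data$voxels * vv / 1000) |>
    select("pu", "name", "lobe", "hemisphere", "voxels", "volume_cm3")
  attr(out, "voxel_volume_mm3") <- vv
  attr(out, "species") <- labelmap$species
  out
}

#' Aggregate a volume table
#'
#' @param volumes Output of [compute_volumes()] (possibly row-bound over
#'   hemispheres).
#' @param by `"lobe"`, `"hemisphere"` or `"total"`.
#' @return A tibble of summed voxel counts and volumes; sums preserve the
#'   total exactly (integer voxel arithmetic).
#' @export
aggregate_volumes <- function(volumes, by = c("lobe", "hemisphere", "total")) {
  by <- tryCatch(match.arg(by),
                 error = function(e) abort("Unknown aggregation key; use lobe, hemisphere or total.",
                                           class = "hoa_usage_error"))
  keys <- switch(by, lobe = c("lobe", "hemisphere"), hemisphere = "hemisphere",
                 total = character())
  volumes |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    summarise(voxels = sum(.data$voxels),
              volume_cm3 = sum(.data$volume_cm3), .groups = "drop")
}

#' Left-right volume asymmetry index
#'
#' The standard laterality quotient `(L - R) / ((L + R) / 2)` per
#' parcellation unit (an extension beyond the atlas tables; the source
#' volumetry reports raw volumes only). Units present in only one
#' hemisphere are skipped with a note.
#'
#' @param volumes A volume table containing both hemispheres (row-bind of
#'   two [compute_volumes()] results).
#' @return A tibble `pu`, `left_cm3`, `right_cm3`, `asymmetry`; skipped
#'   one-sided units are recorded in attribute `skipped`.
#' @export
volume_asymmetry <- function(volumes) {
  wide <- volumes |>
    select("pu", "hemisphere", "volume_cm3") |>
    tidyr::pivot_wider(names_from = "hemisphere", values_from = "volume_cm3")
  for (side in c("left", "right")) {
    if (!side %in% names(wide)) wide[[side]] <- NA_real_
  }
  skipped <- wide$pu[is.na(wide$left) | is.na(wide$right)]
  out <- wide |>
    filter(!is.na(.data$left), !is.na(.data$right)) |>
    mutate(asymmetry = ifelse(.data$left + .data$right > 0,
                              (.data$left - .data$right) / ((.data$left + .data$right) / 2),
                              0)) |>
    select("pu", left_cm3 = "left", right_cm3 = "right", "asymmetry")
  attr(out, "skipped") <- skipped
  out
}

#' Load the packaged single-subject reference volumes
#'
#' @param species `"human"` or `"macaque"`.
#' @return A tibble `pu`, `right_cm3`, `left_cm3` (73 and 40 rows).
#' @examples
#' ref <- reference_volumes("human")
#' ref[ref$pu == "AGa", ]
#' @export
reference_volumes <- function(species = c("human", "macaque")) {
  species <- match.arg(species)
  path <- file.path(pkg_extdata("reference"), paste0(species, "_volumes.tsv"))
  readr::read_tsv(path, col_types = "cdd", progress = FALSE)
}

#' Compare computed volumes against the packaged reference table
#'
#' Purely descriptive: the reference volumes come from a single real MRI
#' session and are not expected to be reproduced by phantom data.
#'
#' @param volumes Output of [compute_volumes()].
#' @param species Reference species; must match the volume table's.
#' @return A tibble with per-unit absolute and relative differences against
#'   the reference column for the matching hemisphere; unmatched unit ids
#'   are listed in attribute `unmatched`.
#' @export
compare_to_reference <- function(volumes, species = c("human", "macaque")) {
  species <- match.arg(species)
  vsp <- attr(volumes, "species")
  if (!is.null(vsp) && !identical(vsp, species)) {
    abort(sprintf("Volume table is %s but reference is %s.", vsp, species),
          class = "hoa_input_error")
  }
  ref <- reference_volumes(species)
  side <- unique(volumes$hemisphere)[1]
  ref_col <- if (identical(side, "left")) "left_cm3" else "right_cm3"
  joined <- volumes |> left_join(ref, by = "pu")
  unmatched <- joined$pu[is.na(joined[[ref_col]])]
  out <- joined |>
    filter(!is.na(.data[[ref_col]])) |>
    mutate(reference_cm3 = .data[[ref_col]],
           diff_cm3 = .data$volume_cm3 - .data$reference_cm3,
           rel_diff = ifelse(.data$reference_cm3 > 0,
                             .data$diff_cm3 / .data$reference_cm3, NA_real_)) |>
    select("pu", "hemisphere", "volume_cm3", "reference_cm3", "diff_cm3", "rel_diff")
  attr(out, "unmatched") <- unmatched
  out
}

#' Bar chart of regional volumes by lobe
#'
#' @param volumes Output of [compute_volumes()].
#' @return A ggplot object.
#' @export
plot_volumes <- function(volumes) {
  ggplot2::ggplot(volumes,
                  ggplot2::aes(x = stats::reorder(.data$pu, .data$volume_cm3),
                               y = .data$volume_cm3, fill = .data$lobe)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~lobe, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "volume (cm³)", fill = "lobe") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
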