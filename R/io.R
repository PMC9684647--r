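#' @title Readers and writers
#' @name io
#' @description
#' Label volumes travel as NIfTI-1 with an integer datatype plus a
#' tab-separated sidecar lookup (code, unit id, name, lobe, hemisphere,
#' species) and a JSON provenance record; traces and events as TSV.
#' All writers are deterministic: stable row order, fixed formatting.
NULL

#' Write / read a label volume (NIfTI + sidecar lookup)
#'
#' @param labelmap An `hoa_labelmap`.
#' @param path Output path for the `.nii.gz` volume; the sidecar lookup is
#'   written next to it as `<path>.lut.tsv` and provenance as
#'   `<path>.json`.
#' @return `write_label_volume()` returns `path` invisibly;
#'   `read_label_volume()` returns an `hoa_labelmap`.
#' @export
write_label_volume <- function(labelmap, path) {
  stopifnot(inherits(labelmap, "hoa_labelmap"))
  img <- RNifti::asNifti(labelmap$labels)
  RNifti::pixdim(img) <- labelmap$frame$voxel_mm
  RNifti::writeNifti(img, path, datatype = "int16")
  lut <- labelmap$lut |> mutate(species = labelmap$species)
  readr::write_tsv(lut, paste0(path, ".lut.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(tool = "hoacompare", version = as.character(utils::packageVersion("hoacompare")),
         species = labelmap$species, side = labelmap$frame$side,
         voxel_mm = labelmap$frame$voxel_mm, origin = labelmap$frame$origin,
         empty_units = labelmap$empty_units,
         provenance = labelmap$provenance["merged"]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (any(arr != round(arr))) {
    abort("Label volume contains non-integer data.", class = "hoa_format_error")
  }
  meta_path <- paste0(path, ".json")
  lut_path <- paste0(path, ".lut.tsv")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  vox <- RNifti::pixdim(img)[1:3]
  frame <- hemisphere_frame(dim(arr), voxel_mm = vox,
                            origin = meta$origin %||% c(0, 0, 0),
                            side = meta$side %||% "right")
  if (!file.exists(lut_path)) {
    warn("No sidecar lookup found; label codes are opaque.")
    codes <- sort(unique(arr[arr > 0]))
    lut <- tibble(code = as.integer(codes), pu = as.character(codes),
                  name = NA_character_, lobe = NA_character_, side = frame$side)
  } else {
    lut <- readr::read_tsv(lut_path, col_types = readr::cols(code = "i", .default = "c"),
                           progress = FALSE)
    orphan <- setdiff(unique(arr[arr > 0]), lut$code)
    if (length(orphan)) {
      warn(sprintf("Label codes missing from sidecar lookup: %s",
                   paste(orphan, collapse = ", ")))
    }
  }
  new_labelmap(frame, array(as.integer(round(arr)), dim(arr)),
               lut |> select("code", "pu", "name", "lobe", "side"),
               meta$species %||% "human",
               empty_units = meta$empty_units %||% character())
}

#' Write / read hemisphere annotations (traces and events TSV)
#'
#' @param hemi An `hoa_hemisphere`.
#' @param traces_path,events_path,ribbon_path File paths. The ribbon is a
#'   NIfTI volume of surface-class codes; parameters travel in
#'   `<ribbon_path>.json`.
#' @param species Species of the ontology the annotations belong to.
#' @return `write_annotations()` returns the paths invisibly;
#'   `read_annotations()` returns an `hoa_hemisphere`.
#' @export
write_annotations <- function(hemi, traces_path, events_path, ribbon_path) {
  stopifnot(inherits(hemi, "hoa_hemisphere"))
  readr::write_tsv(hemi$traces, traces_path, progress = FALSE)
  readr::write_tsv(hemi$events, events_path, progress = FALSE)
  img <- RNifti::asNifti(hemi$ribbon)
  RNifti::pixdim(img) <- hemi$frame$voxel_mm
  RNifti::writeNifti(img, ribbon_path, datatype = "int16")
  jsonlite::write_json(
    list(tool = "hoacompare", species = hemi$species, side = hemi$frame$side,
         voxel_mm = hemi$frame$voxel_mm, origin = hemi$frame$origin,
         params = hemi$params, absent_sulci = hemi$absent_sulci),
    paste0(ribbon_path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(traces_path, events_path, ribbon_path))
}

#' @rdname write_annotations
#' @export
read_annotations <- function(traces_path, events_path, ribbon_path,
                             species = c("human", "macaque")) {
  species <- match.arg(species)
  traces <- readr::read_tsv(traces_path,
                            col_types = readr::cols(sulcus = "c", instance = "i",
                                                    point = "i", x = "d", y = "d", z = "d"),
                            progress = FALSE)
  events <- readr::read_tsv(events_path,
                            col_types = readr::cols(landmark = "c", x = "d",
                                                    y = "d", z = "d"),
                            progress = FALSE)
  img <- RNifti::readNifti(ribbon_path)
  meta_path <- paste0(ribbon_path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  frame <- hemisphere_frame(dim(img), voxel_mm = RNifti::pixdim(img)[1:3],
                            origin = meta$origin %||% c(0, 0, 0),
                            side = meta$side %||% "right")
  ont <- load_ontology(species)
  bad <- setdiff(unique(traces$sulcus), ont$sulci$abbrev)
  if (length(bad)) {
    abort(sprintf("Trace references unknown sulcus id(s): %s",
                  paste(bad, collapse = ", ")), class = "hoa_input_error")
  }
  hemi <- annotated_hemisphere(frame, array(as.integer(as.array(img)), dim(img)),
                               traces, events, species,
                               params = meta$params %||% list(),
                               absent_sulci = unlist(meta$absent_sulci) %||% character())
  # duplicated-instance legality is part of annotation checking
  check_annotation(ont, hemi)
  hemi
}

#' Write a volume table as TSV
#'
#' @param volumes Output of [compute_volumes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(volumes, path) {
  out <- volumes |> mutate(volume_cm3 = sprintf("%.2f", .data$volume_cm3))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
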