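#' @title Atlas ontologies: loading and querying
#' @name ontology
#' @description
#' The package ships the revised Harvard-Oxford cortical parcellation
#' ontologies for the human (hHOA2.0, 73 parcellation units) and the rhesus
#' macaque (mHOA2.0, 40 parcellation units) as plain-text tables: the unit
#' inventories, the limiting sulci with their Neuronames/TNA2/FIPAT
#' identifiers, the coronal limiting planes and surface landmarks, the
#' derived border lines, the per-unit border definitions, and the
#' human-macaque-Brodmann-Walker equivalence table. [load_ontology()]
#' compiles these into a single cross-referenced object.
NULL

.hoa_slot_names <- c("anterior", "posterior", "medial_inferior", "lateral_superior")

na_marker <- "n/a"
nd_marker <- "n.d."

ontology_dir <- function(source_path = NULL) {
  if (!is.null(source_path)) return(source_path)
  pkg_extdata("ontology")
}

# Locate packaged data; an option allows sourcing the package tree directly
# during development.
pkg_extdata <- function(...) {
  override <- getOption("hoacompare.extdata", NULL)
  if (!is.null(override)) return(file.path(override, ...))
  system.file("extdata", ..., package = "hoacompare", mustWork = TRUE)
}

read_onto_tsv <- function(dir, file) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    abort(sprintf("Ontology source file not found: %s", path),
          class = "hoa_input_error")
  }
  out <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, na = character()),
    error = function(e) abort(sprintf("Failed to parse %s: %s", file, conditionMessage(e)),
                              class = "hoa_parse_error")
  )
  if (nrow(out) == 0L) {
    abort(sprintf("Ontology source file %s is empty.", file), class = "hoa_parse_error")
  }
  out
}

# Symbols as printed in the border tables that differ from the sulcus
# inventory abbreviation (or that shorthand a plane).
.human_aliases <- c(prc = "prs", poc = "pcs", circ = "cir", Ci = "ci",
                    S45 = "S45D", CPJ = "CP J")
.macaque_aliases <- c(ips = "itps", IPS = "itps", ls = "lf", ios = "iocs",
                      iocs = "iocs", cfs = "cgs", HPC = "hpc", M = "CP M",
                      hpc = "hpc")

.derived_ids <- c("S45D", "I45D", "CIL", "CSL", "HM", "SPRCL", "IPRCL",
                  "SPOCL", "IPOCL", "PAL", "ASL", "APL", "STP_MID")
.landmark_refs <- c("BF", "SEP", "Ant end insula", "Post end insula")

#' Parse one border-table cell into structured border references
#'
#' Cells contain comma-separated references to sulci, coronal planes, derived
#' lines or landmarks, e.g. `"CP E, im"`, `"S45D/lorb"`, `"ccs (ant)"`,
#' `"1/2 STP"`, or the explicit not-applicable marker `"n/a"`.
#'
#' @param cell Character scalar, the raw cell text.
#' @param species `"human"` or `"macaque"`.
#' @return A tibble with columns `kind`, `target`, `qualifier`, `raw`;
#'   zero rows for an `"n/a"` cell.
#' @keywords internal
parse_border_cell <- function(cell, species) {
  raw0 <- trimws(cell)
  if (identical(raw0, na_marker) || raw0 == "") {
    return(tibble(kind = character(), target = character(),
                  qualifier = character(), raw = character()))
  }
  txt <- gsub("1/2 STP", "STP_MID", raw0, fixed = TRUE)
  toks <- trimws(unlist(strsplit(txt, ",", fixed = TRUE)))
  toks <- unlist(lapply(toks, function(t) {
    # "S45D/lorb" names two alternative borders in one cell
    if (grepl("/", t, fixed = TRUE) && !grepl("n/a", t, fixed = TRUE)) {
      trimws(unlist(strsplit(t, "/", fixed = TRUE)))
    } else t
  }))
  toks <- toks[toks != ""]
  aliases <- if (species == "human") .human_aliases else .macaque_aliases
  purrr::map_dfr(toks, function(t) {
    qual <- NA_character_
    m <- regmatches(t, regexec("^(.*?)\\s*\\(([^)]*)\\)$", t))[[1]]
    if (length(m) == 3L && !(m[2] %in% c("Ant end", "Post end"))) {
      t <- trimws(m[2]); qual <- m[3]
    }
    if (t %in% names(aliases)) t <- unname(aliases[[t]])
    kind <- if (grepl("^CP\\s", t) || grepl("^Pl\\s", t)) "plane"
    else if (t %in% .derived_ids) "derived-line"
    else if (t %in% .landmark_refs) "landmark"
    else "sulcus"
    tibble(kind = kind, target = t, qualifier = qual, raw = raw0)
  })
}

#' Load a packaged (or user-supplied) parcellation ontology
#'
#' Reads the plain-text ontology tables for one species and compiles them
#' into a cross-referenced `hoa_ontology` object. Loading does not validate;
#' run [validate_ontology()] for consistency checks.
#'
#' @param species `"human"` or `"macaque"`.
#' @param source_path Optional directory holding the ontology TSV files;
#'   defaults to the tables packaged with hoacompare.
#' @return An object of class `hoa_ontology`: a list with tibbles `units`,
#'   `sulci`, `landmarks`, `derived_lines`, `borders`, `surfaces` and the
#'   species-shared `equivalences`.
#' @examples
#' ont <- load_ontology("human")
#' nrow(ont$units)
#' @export
load_ontology <- function(species = c("human", "macaque"), source_path = NULL) {
  species <- match.arg(species)
  dir <- ontology_dir(source_path)
  pre <- species

  units <- read_onto_tsv(dir, paste0(pre, "_units.tsv"))
  need <- c("id", "name", "lobe", "modified")
  if (!all(need %in% names(units))) {
    abort(sprintf("Malformed unit table: expected columns %s",
                  paste(need, collapse = ", ")), class = "hoa_parse_error")
  }
  units <- units |>
    mutate(modified = as.logical(.data$modified),
           merge_partner = dplyr::case_when(
             pre == "human" & .data$id == "FOCL" ~ "F3o",
             pre == "human" & .data$id == "F3o" ~ "FOCL",
             TRUE ~ NA_character_),
           functional_type = NA_character_,
           row = dplyr::row_number())

  sulci <- read_onto_tsv(dir, paste0(pre, "_sulci.tsv")) |>
    mutate(may_duplicate = as.logical(.data$may_duplicate),
           provisional = as.logical(.data$provisional))
  bad_id <- function(v) !(grepl("^[0-9]+$", v) | v == nd_marker)
  for (col in c("neuronames_id", "tna2_id", "fipat_id")) {
    if (any(bad_id(sulci[[col]]))) {
      row <- sulci$abbrev[which(bad_id(sulci[[col]]))[1]]
      abort(sprintf("Malformed sulcus record '%s': field %s must be a positive integer or '%s'.",
                    row, col, nd_marker), class = "hoa_parse_error")
    }
  }

  landmarks <- read_onto_tsv(dir, paste0(pre, "_landmarks.tsv"))
  if (species == "macaque") {
    landmarks <- bind_rows(landmarks, tibble(
      id = c("Ant end insula", "Post end insula"),
      kind = "surface-landmark",
      defining_event = c("Insular cortex, anterior limit",
                         "Insular cortex, posterior limit")))
  }

  derived <- read_onto_tsv(dir, "derived_lines.tsv") |>
    filter(.data$species %in% c("both", !!species)) |>
    select(-"species")

  braw <- read_onto_tsv(dir, paste0(pre, "_borders.tsv"))
  slot_cols <- setdiff(names(braw), "pu")
  if (length(slot_cols) != 4L) {
    abort("Border table must have a pu column plus four border slots.",
          class = "hoa_parse_error")
  }
  # Printed column order maps onto the canonical slot names: the macaque
  # table prints Superior/Inferior/Anterior/Posterior, the human table
  # Ant/Post/Med-Inf/Lat-Sup.
  slot_map <- if (species == "human") {
    setNames(.hoa_slot_names, slot_cols)
  } else {
    setNames(c("lateral_superior", "medial_inferior", "anterior", "posterior"),
             slot_cols)
  }
  borders <- purrr::map_dfr(seq_len(nrow(braw)), function(i) {
    purrr::map_dfr(slot_cols, function(sc) {
      refs <- parse_border_cell(braw[[sc]][i], species)
      refs$pu <- braw$pu[i]
      refs$slot <- unname(slot_map[sc])
      refs$not_applicable <- nrow(refs) == 0L &&
        identical(trimws(braw[[sc]][i]), na_marker)
      if (nrow(refs) == 0L) {
        refs <- tibble(kind = NA_character_, target = NA_character_,
                       qualifier = NA_character_, raw = trimws(braw[[sc]][i]),
                       pu = braw$pu[i], slot = unname(slot_map[sc]),
                       not_applicable = identical(trimws(braw[[sc]][i]), na_marker))
      }
      refs
    })
  }) |>
    select("pu", "slot", "kind", "target", "qualifier", "raw", "not_applicable")

  surfaces <- read_onto_tsv(dir, paste0(pre, "_surfaces.tsv"))

  eq_raw <- read_onto_tsv(dir, "equivalences.tsv")
  equivalences <- parse_equivalences(eq_raw)

  structure(
    list(species = species, units = units, sulci = sulci,
         landmarks = landmarks, derived_lines = derived, borders = borders,
         surfaces = surfaces, equivalences = equivalences),
    class = "hoa_ontology")
}

#' @export
print.hoa_ontology <- function(x, ...) {
  cat(sprintf("<hoa_ontology> %s: %d parcellation units, %d sulci, %d landmarks, %d derived lines\n",
              x$species, nrow(x$units), nrow(x$sulci), nrow(x$landmarks),
              nrow(x$derived_lines)))
  invisible(x)
}

#' Validate an ontology for internal consistency
#'
#' Checks reference closure (every border reference resolves to a sulcus,
#' landmark or derived line of the same species), id uniqueness, border-slot
#' completeness (each slot populated or explicitly not applicable),
#' merge-partner symmetry and equivalence-table integrity. Problems are
#' reported, not thrown.
#'
#' @param ontology An `hoa_ontology`.
#' @return A list of class `hoa_validation` with the unit count, per-lobe
#'   counts, and character vectors of findings (`unresolved`,
#'   `duplicate_ids`, `incomplete_slots`, `equivalence_problems`).
#' @examples
#' rep <- validate_ontology(load_ontology("human"))
#' rep$n_units
#' length(rep$unresolved)
#' @export
validate_ontology <- function(ontology) {
  stopifnot(inherits(ontology, "hoa_ontology"))
  known <- c(ontology$sulci$abbrev, ontology$landmarks$id,
             ontology$derived_lines$id)
  refs <- ontology$borders |> filter(!is.na(.data$target))
  plane_known <- ontology$landmarks$id
  unresolved <- character()
  for (i in seq_len(nrow(refs))) {
    k <- refs$kind[i]; tg <- refs$target[i]
    ok <- switch(k,
                 plane = tg %in% plane_known,
                 sulcus = tg %in% ontology$sulci$abbrev,
                 `derived-line` = tg %in% ontology$derived_lines$id,
                 landmark = tg %in% ontology$landmarks$id,
                 FALSE)
    if (!ok) unresolved <- c(unresolved, sprintf("%s[%s]: %s", refs$pu[i], refs$slot[i], tg))
  }
  dup <- ontology$units$id[duplicated(ontology$units$id)]

  slot_tab <- ontology$borders |>
    group_by(.data$pu, .data$slot) |>
    summarise(ok = any(!is.na(.data$target)) | any(.data$not_applicable),
              .groups = "drop")
  missing_slots <- slot_tab |> filter(!.data$ok)
  per_pu <- ontology$borders |> distinct(.data$pu, .data$slot)
  incomplete <- c(
    sprintf("%s[%s]: empty", missing_slots$pu, missing_slots$slot),
    {
      cnt <- per_pu |> count(.data$pu)
      sprintf("%s: %d slots", cnt$pu[cnt$n != 4L], cnt$n[cnt$n != 4L])
    })

  mp <- ontology$units |> filter(!is.na(.data$merge_partner))
  merge_problems <- character()
  for (i in seq_len(nrow(mp))) {
    back <- ontology$units$merge_partner[ontology$units$id == mp$merge_partner[i]]
    if (length(back) != 1L || is.na(back) || back != mp$id[i]) {
      merge_problems <- c(merge_problems, mp$id[i])
    }
  }

  eq <- ontology$equivalences
  eqp <- character()
  if (ontology$species == "human") {
    bad <- setdiff(eq$hhoa_pu, ontology$units$id)
    if (length(bad)) eqp <- c(eqp, sprintf("hHOA PU not in ontology: %s", bad))
    if (anyDuplicated(eq$hhoa_pu)) {
      eqp <- c(eqp, sprintf("duplicate hHOA rows: %s",
                            paste(unique(eq$hhoa_pu[duplicated(eq$hhoa_pu)]), collapse = ", ")))
    }
  } else {
    m_pus <- unique(unlist(eq$mhoa_pu))
    bad <- setdiff(m_pus, ontology$units$id)
    if (length(bad)) eqp <- c(eqp, sprintf("mHOA PU not in ontology: %s", bad))
  }

  lobe_counts <- ontology$units |> count(.data$lobe) |> arrange(.data$lobe)
  structure(
    list(species = ontology$species,
         n_units = nrow(ontology$units),
         lobe_counts = lobe_counts,
         unresolved = unresolved,
         duplicate_ids = dup,
         incomplete_slots = incomplete,
         merge_problems = merge_problems,
         equivalence_problems = eqp),
    class = "hoa_validation")
}

#' @export
print.hoa_validation <- function(x, ...) {
  cat(sprintf("<hoa_validation> %s: %d units; %d unresolved refs; %d duplicate ids; %d incomplete slots\n",
              x$species, x$n_units, length(x$unresolved),
              length(x$duplicate_ids), length(x$incomplete_slots)))
  invisible(x)
}

#' Count parcellation units
#'
#' @param ontology An `hoa_ontology`.
#' @param group_by One of `"none"`, `"lobe"`, `"modified"`.
#' @return A tibble of counts; grouped counts sum to the total.
#' @examples
#' count_units(load_ontology("human"), "lobe")
#' @export
count_units <- function(ontology, group_by = c("none", "lobe", "modified")) {
  stopifnot(inherits(ontology, "hoa_ontology"))
  group_by <- tryCatch(match.arg(group_by),
                       error = function(e) abort("Unknown `group_by`; use none, lobe or modified.",
                                                 class = "hoa_usage_error"))
  u <- ontology$units
  switch(group_by,
         none = tibble(n = nrow(u)),
         lobe = u |> count(.data$lobe, name = "n") |> arrange(.data$lobe),
         modified = u |> count(.data$modified, name = "n") |> arrange(.data$modified))
}

#' Retrieve one parcellation unit with its four border slots
#'
#' @param ontology An `hoa_ontology`.
#' @param pu_id Unit id, e.g. `"AGa"`.
#' @return A list of class `hoa_unit` with the unit's metadata and a named
#'   list `borders` over the four slots (`anterior`, `posterior`,
#'   `medial_inferior`, `lateral_superior`), each a tibble of border
#'   references or an `"n/a"` marker.
#' @examples
#' get_unit(load_ontology("human"), "AGa")$borders$anterior
#' @export
get_unit <- function(ontology, pu_id) {
  stopifnot(inherits(ontology, "hoa_ontology"))
  u <- ontology$units |> filter(.data$id == pu_id)
  if (nrow(u) == 0L) {
    near <- ontology$units$id[agrepl(pu_id, ontology$units$id, max.distance = 0.3) |
                                startsWith(tolower(ontology$units$id), tolower(substr(pu_id, 1, 2)))]
    abort(sprintf("Unknown parcellation unit '%s'.%s", pu_id,
                  if (length(near)) paste0(" Near matches: ", paste(head(near, 5), collapse = ", ")) else ""),
          class = "hoa_lookup_error")
  }
  b <- ontology$borders |> filter(.data$pu == pu_id)
  slots <- lapply(setNames(.hoa_slot_names, .hoa_slot_names), function(s) {
    sl <- b |> filter(.data$slot == s)
    if (all(sl$not_applicable)) na_marker
    else sl |> filter(!is.na(.data$target)) |> select("kind", "target", "qualifier")
  })
  structure(c(as.list(u[1, c("id", "name", "lobe", "modified", "merge_partner")]),
              list(borders = slots, species = ontology$species)),
            class = "hoa_unit")
}

#' @export
print.hoa_unit <- function(x, ...) {
  cat(sprintf("<hoa_unit> %s (%s, %s lobe)\n", x$id, x$name, x$lobe))
  for (s in names(x$borders)) {
    b <- x$borders[[s]]
    lab <- if (identical(b, na_marker)) na_marker else paste(b$target, collapse = ", ")
    cat(sprintf("  %-17s %s\n", paste0(s, ":"), lab))
  }
  invisible(x)
}

#' Serialize an ontology to JSON and back
#'
#' Round-tripping through [ontology_to_json()] and [ontology_from_json()]
#' yields an ontology identical field-by-field.
#'
#' @param ontology An `hoa_ontology`.
#' @param path File to write to / read from.
#' @return `ontology_to_json()` returns `path` invisibly;
#'   `ontology_from_json()` returns an `hoa_ontology`.
#' @export
ontology_to_json <- function(ontology, path) {
  stopifnot(inherits(ontology, "hoa_ontology"))
  payload <- list(schema = "hoa_ontology/1", species = ontology$species,
                  tables = lapply(ontology[setdiff(names(ontology), "species")],
                                  function(tb) as.data.frame(tb)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname ontology_to_json
#' @export
ontology_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "hoa_ontology/1")) {
    abort("Not an hoacompare ontology document.", class = "hoa_parse_error")
  }
  tabs <- lapply(payload$tables, function(df) {
    tb <- as_tibble(df)
    for (col in names(tb)) {
      if (is.list(tb[[col]])) {
        tb[[col]] <- lapply(tb[[col]], function(v) if (is.null(v)) character() else as.character(v))
      } else if (is.logical(tb[[col]]) && all(is.na(tb[[col]])) &&
                 !col %in% c("modified", "may_duplicate", "provisional", "not_applicable")) {
        tb[[col]] <- as.character(tb[[col]])
      }
    }
    tb
  })
  structure(c(list(species = payload$species), tabs), class = "hoa_ontology")
}
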