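#' @title Cross-species and cytoarchitectonic equivalence queries
#' @name equivalence
#' @description
#' Each row of the packaged equivalence table links one human parcellation
#' unit to its major and minor Brodmann areas, its homologous macaque unit(s),
#' the corresponding monkey Brodmann areas and, for the frontal lobe, Walker
#' areas. Minor (parenthesized) cytoarchitectonic designations are kept
#' separate from major ones, and qualifier text such as "(medial)" stays
#' attached to its area label.
NULL

.ba_qualifiers <- c("anterior", "posterior", "medial", "agranular", "granular",
                    "PRGL", "PMv")

#' Parse a printed Brodmann/Walker cell into major and minor area lists
#'
#' @param raw Cell text, e.g. `"8 (9, 6)"`, `"4 (medial), 6 (medial)"`,
#'   `"21 (posterior), (22)"` or `"n.d."`.
#' @return A tibble with columns `area`, `qualifier`, `rank`
#'   (`"major"`/`"minor"`).
#' @keywords internal
parse_ba_cell <- function(raw) {
  out <- tibble(area = character(), qualifier = character(), rank = character())
  txt <- trimws(gsub("\\*+$", "", trimws(raw %||% "")))
  if (txt == "" || txt == "n.d.") return(out)
  # Protect commas inside parentheses, then split top-level tokens.
  prot <- gsub("\\(([^)]*)\\)", "(\\1)", txt)
  depth <- 0L; cut <- integer()
  chars <- strsplit(prot, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L); ends <- c(cut - 1L, length(chars))
  toks <- trimws(substring(prot, starts, ends))
  toks <- toks[toks != ""]
  rows <- list()
  for (tok in toks) {
    groups <- regmatches(tok, gregexpr("\\(([^)]*)\\)", tok))[[1]]
    label <- trimws(gsub("\\(([^)]*)\\)", "", tok))
    qual <- NA_character_
    minors <- character()
    for (g in groups) {
      inner <- trimws(substr(g, 2, nchar(g) - 1))
      if (inner %in% .ba_qualifiers) {
        qual <- inner
      } else {
        minors <- c(minors, trimws(unlist(strsplit(inner, ",", fixed = TRUE))))
      }
    }
    if (nzchar(label)) {
      rows[[length(rows) + 1L]] <- tibble(area = label, qualifier = qual, rank = "major")
    }
    for (m in minors[nzchar(minors)]) {
      rows[[length(rows) + 1L]] <- tibble(area = m, qualifier = NA_character_, rank = "minor")
    }
  }
  bind_rows(out, rows)
}

parse_equivalences <- function(eq_raw) {
  eq_raw |>
    mutate(mhoa_pu = lapply(strsplit(.data$mhoa_pu, ","), trimws),
           human_ba = lapply(.data$human_ba, parse_ba_cell),
           monkey_ba = lapply(.data$monkey_ba, parse_ba_cell),
           walker = lapply(.data$walker, parse_ba_cell),
           footnotes = lapply(strsplit(.data$footnotes, ";"), function(v) v[nzchar(v)]))
}

#' Homologous parcellation units across species
#'
#' Human-to-macaque returns the single equivalence row for that human unit
#' (a row may name more than one macaque unit); macaque-to-human returns all
#' rows whose macaque unit matches, a one-to-many relation.
#'
#' @param ontology An `hoa_ontology` (either species; the equivalence table
#'   is shared).
#' @param pu_id Parcellation unit id in the source species.
#' @param direction `"human_to_macaque"` or `"macaque_to_human"`.
#' @return A tibble of matching equivalence records with list-columns for
#'   the Brodmann/Walker designations. Units absent from the equivalence
#'   table yield an empty result with a warning.
#' @examples
#' ont <- load_ontology("human")
#' homolog(ont, "SMA", "human_to_macaque")$mhoa_pu
#' @export
homolog <- function(ontology, pu_id,
                    direction = c("human_to_macaque", "macaque_to_human")) {
  stopifnot(inherits(ontology, "hoa_ontology"))
  direction <- match.arg(direction)
  eq <- ontology$equivalences
  out <- if (direction == "human_to_macaque") {
    eq |> filter(.data$hhoa_pu == pu_id)
  } else {
    eq |> filter(purrr::map_lgl(.data$mhoa_pu, ~ pu_id %in% .x))
  }
  if (nrow(out) == 0L) {
    warn(sprintf("Parcellation unit '%s' has no equivalence record.", pu_id))
  }
  out
}

#' Find parcellation units carrying a Brodmann area
#'
#' Scans the equivalence table for units whose major (optionally also minor)
#' Brodmann designation includes the queried area. Human queries search the
#' human Brodmann columns, macaque queries the monkey Brodmann columns
#' (Walker areas are a separate nomenclature and are not searched).
#'
#' @param ontology An `hoa_ontology`.
#' @param area Brodmann area label, e.g. `"17"` or `"8B"`.
#' @param species `"human"` or `"macaque"`.
#' @param include_minor Also match minor (parenthesized) designations.
#' @return Character vector of parcellation unit ids (sorted, unique);
#'   empty for unknown areas.
#' @examples
#' brodmann_to_units(load_ontology("human"), "17", "human")
#' @export
brodmann_to_units <- function(ontology, area, species = c("human", "macaque"),
                              include_minor = FALSE) {
  stopifnot(inherits(ontology, "hoa_ontology"))
  species <- match.arg(species)
  query <- trimws(as.character(area))
  if (grepl("-", query, fixed = TRUE)) {
    query <- trimws(strsplit(query, "-", fixed = TRUE)[[1]][1])
  }
  eq <- ontology$equivalences
  col <- if (species == "human") "human_ba" else "monkey_ba"
  hit <- purrr::map_lgl(eq[[col]], function(tb) {
    if (nrow(tb) == 0L) return(FALSE)
    keep <- if (include_minor) rep(TRUE, nrow(tb)) else tb$rank == "major"
    any(tb$area[keep] == query)
  })
  ids <- if (species == "human") eq$hhoa_pu[hit] else unlist(eq$mhoa_pu[hit])
  sort(unique(ids))
}
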