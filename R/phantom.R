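#' @title Phantom specifications and generation
#' @name phantom
#' @description
#' Phantom hemispheres make every stage of the pipeline testable without
#' imaging data: the generator places sulci, landmark events and derived-line
#' anchors at fixed design coordinates and computes the ground-truth label of
#' every ribbon voxel analytically from the same placements, using the same
#' border conventions as the engine (half-open planes, wall voxels on
#' traces).
NULL

#' Create a phantom specification
#'
#' @param species `"human"` or `"macaque"`.
#' @param fixture Named fixture variant; see [fixture_suite()].
#' @param side Hemisphere side.
#' @param lorb_instances Human only: number of lateral orbital sulcus traces
#'   (1 triggers the FOCL/F3o merge, 2 keeps the units separate).
#' @param calc_bank_width Calcarine bank half-height in voxels (0 produces
#'   empty intracalcarine units).
#' @param omega_half_width Half-height of the middle pre/postcentral band.
#' @param seed Random seed recorded in the spec (the generator itself is
#'   deterministic; randomness enters only through [perturb_phantom()]).
#' @return An object of class `hoa_phantom_spec`.
#' @export
phantom_spec <- function(species = c("human", "macaque"), fixture = "full",
                         side = c("right", "left"),
                         lorb_instances = 2L, calc_bank_width = NULL,
                         omega_half_width = 5L, seed = 0L) {
  species <- match.arg(species)
  side <- match.arg(side)
  if (is.null(calc_bank_width)) {
    calc_bank_width <- if (species == "human") 3L else 2L
  }
  structure(list(species = species, fixture = fixture, side = side,
                 lorb_instances = as.integer(lorb_instances),
                 calc_bank_width = as.integer(calc_bank_width),
                 omega_half_width = as.integer(omega_half_width),
                 seed = as.integer(seed)),
            class = "hoa_phantom_spec")
}

#' Generate an annotated phantom hemisphere with ground truth
#'
#' @param spec An [phantom_spec()].
#' @return A list with elements `hemisphere` (an `hoa_hemisphere`) and
#'   `truth` (the analytic ground-truth `hoa_labelmap`). Deterministic:
#'   identical specs yield identical output.
#' @examples
#' ph <- generate_phantom(phantom_spec("macaque"))
#' ph$truth
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "hoa_phantom_spec"))
  switch(spec$species,
         human = generate_human_phantom(spec),
         macaque = generate_macaque_phantom(spec))
}

#' Jitter a phantom's annotations for robustness testing
#'
#' Trace and event coordinates are jittered by a uniform offset of at most
#' `noise` voxels (rounded); the ground truth is kept so that engine output
#' can be compared against it (differences must stay within a one-voxel
#' band around the borders). Jitter larger than half the minimal
#' inter-border spacing is refused.
#'
#' @param hemi An `hoa_hemisphere`.
#' @param noise Maximum jitter magnitude in voxels.
#' @param seed Random seed.
#' @param min_spacing Minimal inter-border spacing of the phantom (voxels).
#' @return A jittered `hoa_hemisphere`.
#' @export
perturb_phantom <- function(hemi, noise, seed = 0L, min_spacing = 2) {
  stopifnot(inherits(hemi, "hoa_hemisphere"))
  if (noise > min_spacing / 2) {
    abort("Jitter exceeds half the minimal inter-border spacing; refusing.",
          class = "hoa_input_error")
  }
  if (noise == 0) return(hemi)
  set.seed(seed)
  jit <- function(n) as.integer(round(stats::runif(n, -noise, noise)))
  traces <- hemi$traces
  per_trace <- traces |> distinct(.data$sulcus, .data$instance) |>
    mutate(dy = jit(n()), dz = jit(n()))
  traces <- traces |>
    left_join(per_trace, by = c("sulcus", "instance")) |>
    mutate(y = pmin(pmax(.data$y + .data$dy, 1L), hemi$frame$dim[2]),
           z = pmin(pmax(.data$z + .data$dz, 1L), hemi$frame$dim[3])) |>
    select(-"dy", -"dz")
  events <- hemi$events |>
    mutate(y = pmin(pmax(.data$y + jit(n()), 1L), hemi$frame$dim[2]))
  annotated_hemisphere(hemi$frame, hemi$ribbon, traces, events, hemi$species,
                       hemi$params, hemi$absent_sulci)
}

#' Canned phantom fixtures
#'
#' @param species `"human"` or `"macaque"`.
#' @return A named list of [phantom_spec()]s: for the human, the full
#'   73-unit fixture, the merged-FOCL/F3o variant (single lateral orbital
#'   sulcus), a degenerate fixture with zero calcarine bank width (empty
#'   intracalcarine units), and a left-hemisphere mirror; for the macaque,
#'   the full 40-unit fixture and its mirror.
#' @export
fixture_suite <- function(species = c("human", "macaque")) {
  species <- match.arg(species)
  if (species == "human") {
    list(full = phantom_spec("human", "full"),
         merged_focl = phantom_spec("human", "merged_focl", lorb_instances = 1L),
         empty_calc = phantom_spec("human", "empty_calc", calc_bank_width = 0L),
         left = phantom_spec("human", "left", side = "left"))
  } else {
    list(full = phantom_spec("macaque", "full"),
         left = phantom_spec("macaque", "left", side = "left"))
  }
}
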