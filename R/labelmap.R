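#' @title Label maps
#' @name labelmap
#' @description
#' A label map is the engine's output: one parcellation-unit label per
#' cortical-ribbon voxel (0 elsewhere), with a lookup table mapping stable
#' integer codes (allocated in ontology table order) to unit ids, names and
#' lobes. `tidy()` returns the per-unit voxel counts as a tibble, `glance()`
#' a one-row summary, and `autoplot()` a coronal-slice view.
NULL

new_labelmap <- function(frame, labels, lut, species, empty_units = character(),
                         provenance = list()) {
  structure(list(frame = frame, labels = labels, lut = lut, species = species,
                 empty_units = empty_units, provenance = provenance),
            class = "hoa_labelmap")
}

#' @export
print.hoa_labelmap <- function(x, ...) {
  n_lab <- sum(x$labels > 0L)
  n_units <- dplyr::n_distinct(x$labels[x$labels > 0L])
  cat(sprintf("<hoa_labelmap> %s, %s side: %d labeled voxels across %d of %d units\n",
              x$species, x$frame$side, n_lab, n_units, nrow(x$lut)))
  if (length(x$empty_units)) {
    cat("  empty units:", paste(x$empty_units, collapse = ", "), "\n")
  }
  invisible(x)
}

mirror_labelmap <- function(lm) {
  dmx <- lm$frame$dim[1]
  frame <- lm$frame
  frame$side <- if (frame$side == "right") "left" else "right"
  lut <- lm$lut; lut$side <- frame$side
  new_labelmap(frame, lm$labels[dmx:1, , , drop = FALSE], lut, lm$species,
               lm$empty_units, lm$provenance)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname labelmap
#' @param x An `hoa_labelmap`.
#' @param ... Unused.
#' @method tidy hoa_labelmap
#' @export
tidy.hoa_labelmap <- function(x, ...) {
  counts <- tabulate(x$labels[x$labels > 0L], nbins = nrow(x$lut))
  x$lut |> mutate(voxels = counts)
}

#' @rdname labelmap
#' @method glance hoa_labelmap
#' @export
glance.hoa_labelmap <- function(x, ...) {
  tibble(species = x$species, side = x$frame$side,
         n_units = nrow(x$lut),
         n_nonempty = dplyr::n_distinct(x$labels[x$labels > 0L]),
         n_voxels = sum(x$labels > 0L),
         n_empty_units = length(x$empty_units))
}

#' Check that a label map is a complete, disjoint partition of the ribbon
#'
#' @param labelmap An `hoa_labelmap`.
#' @param hemi The `hoa_hemisphere` the map was computed on (same frame).
#' @return A list of class `hoa_partition_report`: `coverage` (fraction of
#'   ribbon voxels labeled; 1 for engine output), `overlap_count` (0 by
#'   construction: one label per voxel), `unlabeled` (voxel indices),
#'   `unit_voxels` (tibble of per-unit counts), `n_components` (per-unit
#'   connected-component counts; most units are expected singly connected),
#'   `labels_outside_ribbon`.
#' @export
check_partition <- function(labelmap, hemi) {
  stopifnot(inherits(labelmap, "hoa_labelmap"), inherits(hemi, "hoa_hemisphere"))
  if (!frame_identical(labelmap$frame, hemi$frame)) {
    abort("Label map and hemisphere are on different frames.",
          class = "hoa_input_error")
  }
  rib <- hemi$ribbon > 0L
  lab <- labelmap$labels
  unlabeled <- which(rib & lab == 0L)
  outside <- sum(!rib & lab > 0L)
  coverage <- if (sum(rib) == 0L) 0 else (sum(rib) - length(unlabeled)) / sum(rib)
  dm <- labelmap$frame$dim
  ncomp <- purrr::map_int(seq_len(nrow(labelmap$lut)), function(code) {
    vox <- which(lab == code)
    if (!length(vox)) return(0L)
    mask <- logical(length(lab)); mask[vox] <- TRUE
    k <- 0L
    remaining <- mask
    while (any(remaining)) {
      comp <- grow_component(which.max(remaining), remaining, dm,
                             function(from, to, kk) rep(TRUE, length(from)))
      remaining[comp] <- FALSE
      k <- k + 1L
    }
    k
  })
  structure(list(coverage = coverage,
                 overlap_count = 0L,
                 unlabeled = unlabeled,
                 labels_outside_ribbon = outside,
                 unit_voxels = tidy(labelmap),
                 n_components = labelmap$lut |> mutate(components = ncomp)),
            class = "hoa_partition_report")
}

#' @export
print.hoa_partition_report <- function(x, ...) {
  cat(sprintf("<hoa_partition_report> coverage %.4f, %d overlaps, %d unlabeled, %d labels outside ribbon\n",
              x$coverage, x$overlap_count, length(x$unlabeled),
              x$labels_outside_ribbon))
  multi <- x$n_components |> filter(.data$components > 1L)
  if (nrow(multi)) {
    cat("  multi-component units:",
        paste(sprintf("%s (%d)", multi$pu, multi$components), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot coronal slices of a label map
#'
#' @param object An `hoa_labelmap`.
#' @param slices Posterior-anterior (second axis) slice indices; defaults
#'   to four evenly spaced slices through the labeled extent.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hoa_labelmap
#' @export
autoplot.hoa_labelmap <- function(object, slices = NULL, ...) {
  lab <- object$labels
  ys <- which(apply(lab, 2, function(s) any(s > 0L)))
  if (is.null(slices)) {
    slices <- unique(round(stats::quantile(ys, c(0.2, 0.4, 0.6, 0.8))))
  }
  df <- purrr::map_dfr(slices, function(yy) {
    sl <- lab[, yy, ]
    idx <- which(sl > 0L, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    tibble(x = idx[, 1], z = idx[, 2], code = sl[idx], slice = yy)
  })
  df <- df |> left_join(object$lut, by = "code")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, fill = .data$lobe)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "left-right (voxel)", y = "inferior-superior (voxel)",
                  fill = "lobe",
                  title = sprintf("%s parcellation, %s hemisphere",
                                  object$species, object$frame$side)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
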