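#' Hemisphere voxel coordinate frame
#'
#' Defines the coordinate frame in which a cortical-ribbon volume, sulcal
#' traces and landmark events live. Axes follow the RAS convention: the first
#' axis runs left to right, the second posterior to anterior, the third
#' inferior to superior, so a coronal limiting plane is a set of voxels with a
#' constant second-axis coordinate. Voxel indices used throughout the package
#' are 1-based array indices; world coordinates (in mm) are
#' `origin + (index - 1) * voxel_mm`.
#'
#' @param dim Integer vector of length 3, array dimensions.
#' @param voxel_mm Numeric vector of length 3 (or scalar), voxel edge length
#'   in mm per axis. Must be positive.
#' @param origin World coordinate (mm) of voxel `(1, 1, 1)`.
#' @param side `"left"` or `"right"`.
#' @return An object of class `hoa_frame`.
#' @examples
#' hemisphere_frame(c(96, 128, 96), side = "right")
#' @export
hemisphere_frame <- function(dim, voxel_mm = 1, origin = c(0, 0, 0),
                             side = c("right", "left")) {
  side <- match.arg(side)
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) {
    abort("`dim` must be three positive integers.", class = "hoa_input_error")
  }
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(!is.finite(voxel_mm)) || any(voxel_mm <= 0)) {
    abort("`voxel_mm` must be positive.", class = "hoa_input_error")
  }
  structure(
    list(dim = dim, voxel_mm = voxel_mm, origin = rep_len(as.numeric(origin), 3L),
         side = side),
    class = "hoa_frame"
  )
}

#' @export
print.hoa_frame <- function(x, ...) {
  cat(sprintf("<hoa_frame> %s hemisphere, %d x %d x %d voxels at %.3g x %.3g x %.3g mm\n",
              x$side, x$dim[1], x$dim[2], x$dim[3],
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' @param frame A [hemisphere_frame()].
#' @param vox,world A matrix or data frame with columns/3 columns x, y, z.
#' @return A matrix of the converted coordinates.
#' @keywords internal
voxel_to_world <- function(frame, vox) {
  vox <- as.matrix(vox)
  sweep(sweep(vox - 1, 2, frame$voxel_mm, "*"), 2, frame$origin, "+")
}

#' @rdname voxel_to_world
#' @keywords internal
world_to_voxel <- function(frame, world) {
  world <- as.matrix(world)
  sweep(sweep(world, 2, frame$origin, "-"), 2, frame$voxel_mm, "/") + 1
}

frame_identical <- function(a, b) {
  identical(a$dim, b$dim) && isTRUE(all.equal(a$voxel_mm, b$voxel_mm)) &&
    isTRUE(all.equal(a$origin, b$origin)) && identical(a$side, b$side)
}
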