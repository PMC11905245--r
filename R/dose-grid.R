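#' A 3-D dose grid
#'
#' A regular scalar dose grid: a 3-D array of doses (Gy) with voxel
#' spacing (mm) and the physical coordinate of the center of voxel
#' `[1, 1, 1]`.
#'
#' @param values 3-D numeric array of dose in Gy, all values >= 0.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm (a scalar is
#'   recycled).
#' @param origin coordinates (mm) of the first voxel center.
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  stop_if(!is.array(values) || length(dim(values)) != 3L,
          "values must be a 3-D array")
  stop_if(anyNA(values) || any(values < 0), "doses must be nonnegative")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stop_if(length(spacing) != 3L || any(spacing <= 0),
          "spacing must be 3 positive numbers (mm)")
  stop_if(length(origin) != 3L, "origin must be a length-3 mm triplet")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels @ %g x %g x %g mm, dose %.2f-%.2f Gy\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$values), max(x$values)))
  invisible(x)
}

# voxel volume in cc (1 cc = 1000 mm^3)
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

# total grid volume in cc
grid_volume_cc <- function(grid) length(grid$values) * voxel_volume_cc(grid)

#' A voxelized structure mask
#'
#' A boolean mask congruent with a [dose_grid], marking the voxels whose
#' centers lie inside the structure (binary voxel-center membership; no
#' partial-volume weighting).
#'
#' @param mask 3-D logical array, same dimensions as the dose grid.
#' @param grid the [dose_grid] the mask refers to.
#' @param name structure label (e.g. `"PTV"`, `"spinal_cord"`).
#' @return an object of class `structure_mask` with derived `volume_cc`.
#' @export
structure_mask <- function(mask, grid, name = "structure") {
  stop_if(!inherits(grid, "dose_grid"), "grid must be a dose_grid")
  stop_if(!is.array(mask) || !is.logical(mask),
          "mask must be a logical array")
  stop_if(!identical(dim(mask), dim(grid$values)),
          "mask shape must equal the dose grid shape")
  structure(
    list(mask = mask, name = name, spacing = grid$spacing,
         volume_cc = sum(mask) * voxel_volume_cc(grid)),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s: %d voxels, %.2f cc\n",
              x$name, sum(x$mask), x$volume_cc))
  invisible(x)
}

#' Voxel-center coordinate arrays of a grid
#'
#' @param grid a [dose_grid].
#' @return a list of numeric vectors `x`, `y`, `z` (mm), one coordinate per
#'   voxel index along each axis.
#' @export
grid_axes <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3])
}

# squared distance of every voxel center to a point, as a 3-D array
grid_dist2 <- function(grid, center) {
  ax <- grid_axes(grid)
  dx2 <- (ax$x - center[1])^2
  dy2 <- (ax$y - center[2])^2
  dz2 <- (ax$z - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Spherical structure mask on a grid
#'
#' @param grid a [dose_grid].
#' @param center sphere center (mm).
#' @param radius sphere radius (mm).
#' @param name structure label.
#' @return a [structure_mask] of the voxels whose centers fall inside the
#'   sphere.
#' @export
sphere_mask <- function(grid, center, radius, name = "sphere") {
  structure_mask(grid_dist2(grid, center) <= radius^2, grid, name)
}

#' Finite-cylinder structure mask on a grid (axis parallel to z)
#'
#' @param grid a [dose_grid].
#' @param center cylinder center (mm).
#' @param radius cylinder radius (mm).
#' @param length cylinder length along z (mm).
#' @param name structure label.
#' @return a [structure_mask].
#' @export
cylinder_mask <- function(grid, center, radius, length, name = "cylinder") {
  ax <- grid_axes(grid)
  dx2 <- (ax$x - center[1])^2
  dy2 <- (ax$y - center[2])^2
  in_xy <- outer(dx2, dy2, `+`) <= radius^2
  in_z <- abs(ax$z - center[3]) <= length / 2
  m <- array(FALSE, dim(grid$values))
  m[] <- as.vector(outer(in_xy, in_z, `&`))
  structure_mask(m, grid, name)
}
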