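#' Define a voxel grid
#'
#' A grid is a regular, axis-aligned voxel lattice in patient coordinates.
#' Arrays over a grid are indexed `(z, y, x)` = (superior--inferior,
#' anterior--posterior, left--right); `origin` is the mm coordinate of the
#' center of voxel `(1, 1, 1)`, in the same axis order. Point coordinates
#' elsewhere in the package are `(x, y, z)` mm.
#'
#' The default grid is 165 x 176 x 176 voxels at 2 mm isotropic spacing,
#' the resolution and extent used for the network input.
#'
#' @param shape integer vector of 3 voxel counts `(nz, ny, nx)`.
#' @param spacing numeric vector of 3 voxel sizes in mm `(dz, dy, dx)`;
#'   a scalar is recycled.
#' @param origin mm coordinate `(z, y, x)` of the first voxel center.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(shape = c(48, 48, 48), spacing = 3)
#' prod(g$spacing) # voxel volume in mm^3
#' @export
grid_spec <- function(shape = c(165L, 176L, 176L), spacing = c(2, 2, 2),
                      origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    abort("input_error", "grid spacing must be positive and finite")
  if (any(shape < 1L))
    abort("input_error", "grid shape must be >= 1 voxel per axis")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %.3g x %.3g x %.3g mm (z,y,x)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# Coordinate vectors of voxel centers along each axis.
grid_axes <- function(grid) {
  list(z = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       x = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}

# Grid of given shape/spacing whose window is centered on a point
# (cz, cy, cx) in mm.
grid_centered_at <- function(center_zyx, shape, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  origin <- center_zyx - (shape - 1) / 2 * spacing
  grid_spec(shape = shape, spacing = spacing, origin = origin)
}

# Voxel volume in mm^3.
voxel_volume <- function(grid) prod(grid$spacing)

# (x, y, z) mm coordinates of the voxels flagged TRUE in `mask` (or of all
# voxels when mask is NULL), as an n x 3 matrix.
voxel_coords <- function(grid, mask = NULL) {
  ax <- grid_axes(grid)
  if (is.null(mask)) {
    idx <- which(array(TRUE, grid$shape))
  } else {
    idx <- which(mask)
  }
  ijk <- arrayInd(idx, grid$shape)
  cbind(x = ax$x[ijk[, 3]], y = ax$y[ijk[, 2]], z = ax$z[ijk[, 1]])
}

empty_mask <- function(grid) array(FALSE, dim = grid$shape)

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
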