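# The 3-channel network input: coded label volume plus CTV and OAR distance
# maps relative to the tandem's central axis. Distances stay in raw mm — no
# normalization — so physical size information reaches the classifier.

#' Minimum distance from points to the tandem's central axis
#'
#' Closed-form point-to-segment distance, minimized over the polyline's
#' segments, in 3D. The axis is the raw digitized polyline, not the dilated
#' display tube.
#'
#' @param points n x 3 matrix `(x, y, z)` mm; may have zero rows.
#' @param tandem m x 3 polyline matrix, m >= 2.
#' @return Numeric vector of n distances in mm.
#' @export
distance_to_axis <- function(points, tandem) {
  if (!is.matrix(tandem) || nrow(tandem) < 2L || ncol(tandem) != 3L ||
      any(!is.finite(tandem)))
    abort("malformed_tandem", "tandem must be an n x 3 finite matrix with >= 2 points")
  if (is.null(points) || nrow(points) == 0L) return(numeric(0))
  storage.mode(points) <- "double"
  storage.mode(tandem) <- "double"
  cpp_polyline_distance(points, tandem)
}

#' Build the network input from a label volume and the tandem
#'
#' Channel 1 is the coded label volume (float-cast). Channel 2 carries the
#' distance to the tandem axis at CTV voxels (code 1), channel 3 at OAR
#' voxels (code 3); both are zero elsewhere, including at voxels recoded 2 by
#' tandem precedence. `MASK_ONLY` mode returns channel 1 alone.
#'
#' @param label_volume a `label_volume` from [compose_label_volume()].
#' @param tandem polyline matrix.
#' @param mode `"FULL"` (3 channels) or `"MASK_ONLY"` (1 channel).
#' @return Object of class `model_input`: list with `grid`, `mode` and
#'   numeric 4D array `x` of shape `(nz, ny, nx, channels)`, plus the mm
#'   `spacing` as an attribute on `x`.
#' @export
build_input <- function(label_volume, tandem, mode = c("FULL", "MASK_ONLY")) {
  mode <- match.arg(mode)
  grid <- label_volume$grid
  lab <- label_volume$values
  if (!any(lab == 1L)) abort("missing_target", "label volume has no CTV voxels")
  nch <- if (mode == "FULL") 3L else 1L
  x <- array(0, dim = c(grid$shape, nch))
  x[, , , 1] <- as.numeric(lab)
  if (mode == "FULL") {
    if (!is.matrix(tandem) || nrow(tandem) < 2L)
      abort("malformed_tandem", "tandem polyline needs at least 2 points")
    ax <- grid_axes(grid)
    d <- cpp_grid_polyline_distance(ax$z, ax$y, ax$x, tandem)
    x[, , , 2] <- d * (lab == 1L)
    x[, , , 3] <- d * (lab == 3L)
  }
  attr(x, "spacing") <- grid$spacing
  structure(list(grid = grid, mode = mode, x = x), class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  cat(sprintf("<model_input> %s, %d x %d x %d x %d\n", x$mode,
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], dim(x$x)[4]))
  invisible(x)
}

#' Full anatomy-to-input pipeline for one insertion
#'
#' Rasterizes the structure set on a tandem-centered grid and encodes the
#' channels. This is the preprocessing applied to every insertion before
#' training or inference.
#'
#' @inheritParams rasterize_structure_set
#' @inheritParams build_input
#' @return A `model_input`.
#' @export
prepare_input <- function(ss, shape = c(165L, 176L, 176L), spacing = 2,
                          mode = c("FULL", "MASK_ONLY"), tandem_diameter = 5) {
  mode <- match.arg(mode)
  ras <- rasterize_structure_set(ss, shape = shape, spacing = spacing,
                                 tandem_diameter = tandem_diameter)
  build_input(ras$label, ras$tandem, mode = mode)
}
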