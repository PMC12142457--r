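# Rasterization of planar contours and the tandem tube onto a voxel grid,
# and composition of the coded label volume (0 background, 1 CTV, 2 tandem,
# 3 OAR).

#' Rasterize a stack of planar contours to a binary voxel mask
#'
#' A voxel belongs to the mask iff its center falls inside (even--odd rule)
#' a polygon of the nearest contour plane, and its z lies within that plane's
#' thickness band. The band half-width is half the stack's typical slice
#' spacing — the upper quartile of consecutive z gaps, which stays stable
#' when contour stacks of several components interleave (for a single-slice
#' structure, half the grid z spacing). Nested
#' contours at the same z act as holes; disjoint contours at the same z are
#' unioned.
#'
#' @param slices list of planar contours: `list(z =, vertices = <n x 2 (x, y) mm>)`.
#' @param grid a [grid_spec()].
#' @return Logical array over `grid`.
#' @export
rasterize_structure <- function(slices, grid) {
  if (!length(slices)) return(empty_mask(grid))
  for (sl in slices) {
    if (!is.matrix(sl$vertices) || nrow(sl$vertices) < 3L)
      abort("degenerate_contour", "polygon with < 3 vertices")
  }
  ax <- grid_axes(grid)
  zs <- vapply(slices, function(sl) sl$z, numeric(1))
  uz <- sort(unique(zs))
  # half the typical slice spacing; the upper quartile keeps the band stable
  # when two contour stacks interleave at small relative offsets
  half <- if (length(uz) > 1L) {
    unname(stats::quantile(diff(uz), 0.75)) / 2
  } else {
    grid$spacing[1] / 2
  }
  mask <- empty_mask(grid)
  for (i in seq_along(ax$z)) {
    zi <- ax$z[i]
    d <- abs(uz - zi)
    j <- which.min(d)
    if (d[j] > half + 1e-9) next
    polys <- lapply(slices[zs == uz[j]], function(sl) sl$vertices)
    mask[i, , ] <- cpp_raster_slice(ax$y, ax$x, polys)
  }
  mask
}

#' Rasterize the tandem as a cylinder-of-revolution around its polyline
#'
#' A voxel is inside the tube iff its center lies within `diameter / 2`
#' (3D Euclidean, minimum over segments) of the polyline. The 5 mm default
#' matches how the digitized tandem is thickened for the mask channel.
#'
#' @param tandem n x 3 polyline matrix, columns `(x, y, z)` mm, n >= 2.
#' @param grid a [grid_spec()].
#' @param diameter tube diameter in mm.
#' @return Logical array over `grid`.
#' @export
tandem_tube <- function(tandem, grid, diameter = 5) {
  if (!is.matrix(tandem) || nrow(tandem) < 2L)
    abort("malformed_tandem", "tandem polyline needs at least 2 points")
  ax <- grid_axes(grid)
  d <- cpp_grid_polyline_distance(ax$z, ax$y, ax$x, tandem)
  array(d <= diameter / 2 + 1e-12, dim = grid$shape)
}

#' Compose the coded label volume from structure masks
#'
#' The CTV mask is the union of HR-CTV and (when present) IR-CTV. At
#' overlapping voxels label precedence is tandem (2) > CTV (1) > OAR (3) >
#' background (0), so the tandem stays visible inside the target and targets
#' dominate organs at risk.
#'
#' @param ctv_masks list with element `hr_ctv` and optional `ir_ctv`
#'   (logical arrays), or a single logical array.
#' @param tandem_mask logical array from [tandem_tube()].
#' @param oar_masks named list of logical OAR arrays (possibly empty).
#' @param grid the shared [grid_spec()].
#' @return Object of class `label_volume`: list with `grid` and integer
#'   array `values`.
#' @export
compose_label_volume <- function(ctv_masks, tandem_mask, oar_masks = list(),
                                 grid) {
  if (is.array(ctv_masks)) ctv_masks <- list(hr_ctv = ctv_masks)
  ctv <- ctv_masks$hr_ctv
  if (!is.null(ctv_masks$ir_ctv)) ctv <- ctv | ctv_masks$ir_ctv
  if (is.null(ctv) || !any(ctv))
    abort("missing_target", "CTV mask is empty after HR/IR union")
  values <- array(0L, dim = grid$shape)
  for (m in oar_masks) values[m] <- 3L
  values[ctv] <- 1L
  values[tandem_mask] <- 2L
  structure(list(grid = grid, values = values), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- tabulate(x$values + 1L, nbins = 4L)
  cat(sprintf("<label_volume> %d x %d x %d; CTV %d, tandem %d, OAR %d voxels\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Resample a mask or label array onto a target grid
#'
#' Nearest-neighbor resampling (labels are categorical), with voxels whose
#' nearest source center falls outside the source grid set to background.
#' When part of the labelled volume falls outside the target window the lost
#' voxel count is reported with a warning.
#'
#' @param values logical or integer array over `native_grid`.
#' @param native_grid,target_grid [grid_spec()] objects.
#' @return Array of the same storage mode over `target_grid`.
#' @export
resample_and_crop <- function(values, native_grid, target_grid) {
  tax <- grid_axes(target_grid)
  nn <- function(coord, origin, spacing, n) {
    i <- as.integer(round((coord - origin) / spacing)) + 1L
    i[i < 1L | i > n] <- NA_integer_
    i
  }
  iz <- nn(tax$z, native_grid$origin[1], native_grid$spacing[1], native_grid$shape[1])
  iy <- nn(tax$y, native_grid$origin[2], native_grid$spacing[2], native_grid$shape[2])
  ix <- nn(tax$x, native_grid$origin[3], native_grid$spacing[3], native_grid$shape[3])
  zin <- !is.na(iz); yin <- !is.na(iy); xin <- !is.na(ix)
  out <- array(if (is.logical(values)) FALSE else 0L, dim = target_grid$shape)
  if (any(zin) && any(yin) && any(xin)) {
    out[zin, yin, xin] <- values[iz[zin], iy[yin], ix[xin]]
  }
  n_native <- sum(values != 0)
  # labelled voxels lost by the window, in native-voxel units
  vol_ratio <- voxel_volume(target_grid) / voxel_volume(native_grid)
  n_target <- sum(out != 0) * vol_ratio
  lost <- n_native - n_target
  if (n_native > 0 && lost > 0.05 * n_native) {
    warn_log(sprintf(
      "resample_and_crop: ~%d of %d labelled native voxels fall outside the target window",
      round(lost), n_native))
  }
  out
}

# --- pipeline convenience ----------------------------------------------------

#' Rasterize a structure set onto a tandem-centered grid
#'
#' Builds the target grid (default: the 165 x 176 x 176, 2 mm network grid)
#' centered on the tandem polyline centroid so that all inputs are registered
#' the same way, rasterizes every structure, and composes the label volume.
#'
#' @param ss a [structure_set()].
#' @param shape,spacing target grid geometry.
#' @param tandem_diameter tube diameter in mm.
#' @return list with `grid`, `label` (a `label_volume`), the individual
#'   logical `masks` (hr_ctv, optional ir_ctv, one per present OAR, tandem),
#'   and the `tandem` polyline.
#' @export
rasterize_structure_set <- function(ss, shape = c(165L, 176L, 176L),
                                    spacing = 2, tandem_diameter = 5) {
  ctr <- tandem_centroid(ss$tandem)           # (x, y, z)
  grid <- grid_centered_at(c(ctr[3], ctr[2], ctr[1]), as.integer(shape), spacing)
  masks <- list()
  hr <- ss_get_role(ss, "HR_CTV")
  masks$hr_ctv <- rasterize_structure(hr$slices, grid)
  ir <- ss_get_role(ss, "IR_CTV")
  if (!is.null(ir)) masks$ir_ctv <- rasterize_structure(ir$slices, grid)
  oars <- list()
  for (role in oar_roles()) {
    s <- ss_get_role(ss, role)
    if (!is.null(s)) oars[[tolower(role)]] <- rasterize_structure(s$slices, grid)
  }
  masks$tandem <- tandem_tube(ss$tandem, grid, diameter = tandem_diameter)
  label <- compose_label_volume(masks[intersect(names(masks), c("hr_ctv", "ir_ctv"))],
                                masks$tandem, oars, grid)
  masks <- c(masks, oars)
  list(grid = grid, label = label, masks = masks, tandem = ss$tandem)
}

#' Export a label volume as NIfTI for visual inspection
#'
#' Requires the `RNifti` package.
#' @param lv a `label_volume`.
#' @param path output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_label_nifti <- function(lv, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("input_error", "RNifti is required for NIfTI export")
  img <- RNifti::asNifti(array(as.integer(lv$values), dim = lv$grid$shape),
                         pixdim = lv$grid$spacing, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}
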