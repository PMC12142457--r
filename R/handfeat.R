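# The 20 handcrafted geometric features: CTV volume, lateral extension and
# center-of-mass offset relative to the tandem axis (per axial slice), and
# max/min/average distance of the nearest-2cc volume of each of the five
# OARs to the CTV surface. Fixed column order, documented in
# feature_names().

#' Names and order of the 20 handcrafted features
#' @return Character vector of length 20.
#' @export
feature_names <- function() {
  c("ctv_volume_cc", "lat_ext_avg", "lat_ext_max",
    "com_offset_avg", "com_offset_max",
    as.vector(t(outer(tolower(oar_roles()),
                      c("d2cc_max", "d2cc_min", "d2cc_avg"), paste, sep = "_"))))
}

#' Sentinel distance (mm) recorded for an OAR with no contour
#'
#' Far enough to be dosimetrically irrelevant.
#' @export
missing_oar_sentinel <- 999

#' CTV volume in cc
#'
#' Voxel count times voxel volume.
#' @param ctv_mask logical array (the HR/IR-CTV union).
#' @param grid the mask's [grid_spec()].
#' @return Volume in cc.
#' @export
ctv_volume <- function(ctv_mask, grid) {
  n <- sum(ctv_mask)
  if (n == 0L) abort("missing_target", "empty CTV mask")
  n * voxel_volume(grid) / 1000
}

# Per-axial-slice in-plane geometry of a mask relative to the tandem axis.
# Returns one row per CTV-containing slice: max in-plane distance from the
# axis point to any mask voxel center (lateral extension) and the in-plane
# distance from the slice's voxel centroid to the axis (asymmetry offset).
slice_geometry <- function(mask, tandem, grid) {
  ax <- grid_axes(grid)
  rows <- NULL
  for (i in seq_along(ax$z)) {
    sl <- mask[i, , ]
    if (!any(sl)) next
    axis_pt <- tandem_axis_at(tandem, ax$z[i])
    jk <- which(sl, arr.ind = TRUE)
    yv <- ax$y[jk[, 1]]; xv <- ax$x[jk[, 2]]
    d <- sqrt((xv - axis_pt[1, 1])^2 + (yv - axis_pt[1, 2])^2)
    com <- c(mean(xv), mean(yv))
    rows <- rbind(rows, c(z = ax$z[i], ext = max(d),
                          off = sqrt(sum((com - axis_pt[1, ])^2))))
  }
  as.data.frame(rows)
}

#' Lateral extension of the CTV relative to the tandem axis
#'
#' Per CTV-containing axial slice, the maximum in-plane distance from the
#' tandem axis point on that slice (polyline interpolated; straight-line
#' extension beyond its endpoints) to any CTV voxel center. Returns the mean
#' and maximum across slices.
#'
#' @inheritParams ctv_volume
#' @param tandem tandem polyline matrix.
#' @return `c(avg =, max =)` in mm.
#' @export
lateral_extension <- function(ctv_mask, tandem, grid) {
  if (!any(ctv_mask)) abort("missing_target", "empty CTV mask")
  g <- slice_geometry(ctv_mask, tandem, grid)
  c(avg = mean(g$ext), max = max(g$ext))
}

#' Center-of-mass offset of the CTV from the tandem axis
#'
#' Per axial slice, the in-plane distance between the CTV voxel-center
#' centroid and the tandem axis point: a measure of CTV asymmetry. Returns
#' mean and maximum across CTV-containing slices.
#'
#' @inheritParams lateral_extension
#' @return `c(avg =, max =)` in mm.
#' @export
com_offset <- function(ctv_mask, tandem, grid) {
  if (!any(ctv_mask)) abort("missing_target", "empty CTV mask")
  g <- slice_geometry(ctv_mask, tandem, grid)
  c(avg = mean(g$off), max = max(g$off))
}

#' Distance statistics of the nearest-2cc OAR volume to the CTV surface
#'
#' For every OAR voxel, the unsigned Euclidean distance from its center to
#' the nearest CTV boundary voxel center (0 for OAR voxels inside the CTV).
#' The `floor(2000 mm^3 / voxel volume)` OAR voxels with the smallest
#' distances are selected (all voxels when the OAR is smaller than 2 cc); the
#' maximum, minimum and average distance over that selection are returned.
#' This mirrors the D2cc proximity rationale: the hottest 2 cc of an organ is
#' the part closest to the target.
#'
#' @param oar_mask,ctv_mask logical arrays over `grid`.
#' @param grid the shared [grid_spec()].
#' @return `c(max =, min =, avg =)` in mm.
#' @export
nearest_2cc_distances <- function(oar_mask, ctv_mask, grid) {
  if (!any(ctv_mask)) abort("missing_target", "empty CTV mask")
  if (!any(oar_mask)) abort("input_error", "empty OAR mask")
  boundary <- cpp_boundary_mask(ctv_mask)
  bcoord <- voxel_coords(grid, boundary)
  ocoord <- voxel_coords(grid, oar_mask)
  d <- cpp_min_point_distance(ocoord, bcoord)
  d[ctv_mask[oar_mask]] <- 0      # OAR voxels inside the CTV
  n_sel <- min(length(d), floor(2000 / voxel_volume(grid)))
  # tie-break: smallest distance first, then lexicographic voxel index
  ord <- order(d, seq_along(d))
  sel <- d[ord[seq_len(n_sel)]]
  c(max = max(sel), min = min(sel), avg = mean(sel))
}

#' Assemble the 20-feature vector for one insertion
#'
#' Features are computed on the rasterized masks; OARs with no contour get
#' the `missing_oar_sentinel` (999 mm) for their whole triple, with a
#' warning.
#'
#' @param masks named list of logical arrays: `hr_ctv` (required), optional
#'   `ir_ctv`, and any of `bladder`, `rectum`, `sigmoid`, `small_bowel`,
#'   `large_bowel`.
#' @param tandem tandem polyline matrix.
#' @param grid the shared [grid_spec()].
#' @return Named numeric vector of length 20, ordered as [feature_names()].
#' @export
feature_vector <- function(masks, tandem, grid) {
  ctv <- masks$hr_ctv
  if (is.null(ctv)) abort("missing_target", "masks$hr_ctv is required")
  if (!is.null(masks$ir_ctv)) ctv <- ctv | masks$ir_ctv
  if (!any(ctv)) abort("missing_target", "empty CTV mask")
  out <- c(ctv_volume_cc = ctv_volume(ctv, grid),
           lat_ext = lateral_extension(ctv, tandem, grid),
           com_offset = com_offset(ctv, tandem, grid))
  names(out) <- c("ctv_volume_cc", "lat_ext_avg", "lat_ext_max",
                  "com_offset_avg", "com_offset_max")
  for (role in tolower(oar_roles())) {
    m <- masks[[role]]
    if (is.null(m) || !any(m)) {
      warn_log(sprintf("no %s contour: recording %g mm sentinel", role,
                       missing_oar_sentinel))
      trip <- c(max = missing_oar_sentinel, min = missing_oar_sentinel,
                avg = missing_oar_sentinel)
    } else {
      trip <- nearest_2cc_distances(m, ctv, grid)
    }
    names(trip) <- paste(role, c("d2cc_max", "d2cc_min", "d2cc_avg"), sep = "_")
    out <- c(out, trip)
  }
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Extract features for one structure set
#'
#' Rasterizes on a tandem-centered grid and assembles the feature vector.
#' @param ss a [structure_set()].
#' @param shape,spacing rasterization grid geometry.
#' @return Named numeric vector of length 20.
#' @export
extract_features <- function(ss, shape = c(165L, 176L, 176L), spacing = 2) {
  ras <- rasterize_structure_set(ss, shape = shape, spacing = spacing)
  m <- ras$masks
  m$tandem <- NULL
  feature_vector(m, ras$tandem, ras$grid)
}

#' Feature table for a cohort of structure sets
#'
#' @param cohort a cohort from [generate_cohort()], or a list of
#'   [structure_set()]s.
#' @param shape,spacing rasterization grid geometry.
#' @return data.frame with `patient_id`, `insertion_id`, `y` and the 20
#'   feature columns.
#' @export
cohort_feature_table <- function(cohort, shape = c(165L, 176L, 176L), spacing = 2) {
  sets <- if (!is.null(cohort$structure_sets)) cohort$structure_sets else cohort
  rows <- lapply(sets, function(ss) {
    f <- extract_features(ss, shape = shape, spacing = spacing)
    cbind(data.frame(patient_id = ss$patient_id, insertion_id = ss$insertion_id,
                     y = as.numeric(ss$true_label)),
          as.data.frame(as.list(f)))
  })
  do.call(rbind, rows)
}
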