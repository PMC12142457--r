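# Synthetic pelvic anatomies with a known, analytic ground-truth applicator
# label. The generator emulates post-insertion geometry: a near-vertical
# central tandem, a CTV built from 1-3 stacked ellipsoids of controllable
# volume, lateral extent and left-right asymmetry, and OARs placed
# anatomically (bladder anterior, rectum posterior, sigmoid superior, bowel
# lateral/superior) at controllable gaps. The label follows a geometric rule
# in the spirit of published applicator-selection guidance: an interstitial
# (Syed) applicator is indicated when the CTV is too large, extends too far
# laterally from the tandem, or is too asymmetric for intracavitary dosimetry.

#' Ground-truth rule thresholds
#'
#' Syed iff analytic max lateral extension > `L_max` OR analytic max
#' center-of-mass offset > `delta` OR analytic volume > `V_max`.
#' @param L_max lateral-extension threshold, mm.
#' @param delta asymmetry-offset threshold, mm.
#' @param V_max volume threshold, cc.
#' @export
phantom_rule <- function(L_max = 30, delta = 8, V_max = 60) {
  stopifnot(L_max > 0, delta > 0, V_max > 0)
  list(L_max = L_max, delta = delta, V_max = V_max)
}

#' Describe one synthetic anatomy
#'
#' @param ctv list of 1-3 ellipsoid components, each
#'   `list(center = c(x, y, z) mm, semi = c(ax, ay, az) mm)`. Components are
#'   stacked disjointly along z so the union volume is the sum of component
#'   volumes.
#' @param tandem_length tandem length along SI, mm.
#' @param tandem_bow maximum anterior bow of the tandem, mm.
#' @param oars named list (roles `bladder`, `rectum`, `sigmoid`,
#'   `small_bowel`, `large_bowel`) of `list(gap =, semi = c(x, y, z))`;
#'   `gap` is the mm clearance between the OAR and the CTV bounding extent
#'   along its placement direction. `NULL` entries omit the OAR.
#' @param rule a [phantom_rule()].
#' @param noise contour surface jitter amplitude, mm.
#' @param slice_spacing contour slice spacing, mm (2.5 mm exercises
#'   resampling onto the 2 mm grid).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(ctv, tandem_length = 60, tandem_bow = 2,
                         oars = default_phantom_oars(), rule = phantom_rule(),
                         noise = 1, slice_spacing = 2.5) {
  stopifnot(length(ctv) >= 1L, length(ctv) <= 3L, tandem_length > 0,
            noise >= 0, slice_spacing > 0)
  for (comp in ctv) stopifnot(length(comp$center) == 3L, all(comp$semi > 0))
  for (o in oars) if (!is.null(o)) stopifnot(o$gap >= 0, all(o$semi > 0))
  structure(list(ctv = ctv, tandem_length = tandem_length,
                 tandem_bow = tandem_bow, oars = oars, rule = rule,
                 noise = noise, slice_spacing = slice_spacing),
            class = "phantom_spec")
}

#' Default OAR geometry for the phantom
#' @export
default_phantom_oars <- function() {
  list(bladder = list(gap = 8, semi = c(25, 18, 22)),
       rectum = list(gap = 6, semi = c(14, 12, 30)),
       sigmoid = list(gap = 8, semi = c(16, 14, 12)),
       small_bowel = list(gap = 10, semi = c(20, 16, 14)),
       large_bowel = list(gap = 12, semi = c(18, 14, 16)))
}

# analytic tandem centerline (x, y as functions of z)
tandem_curve <- function(spec, z) {
  cbind(x = rep(0, length(z)),
        y = spec$tandem_bow * sin(pi * z / spec$tandem_length))
}

# Analytic (continuous, pre-jitter) rule quantities, computed from the
# generating parameters rather than any rasterization: union volume in cc,
# max lateral extension and max per-slice centroid offset relative to the
# tandem centerline (boundary sampled densely in angle, slices at 0.5 mm).
phantom_analytics <- function(spec) {
  vol <- sum(vapply(spec$ctv, function(c_) 4 / 3 * pi * prod(c_$semi), numeric(1))) / 1000
  max_ext <- 0; max_off <- 0
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  for (comp in spec$ctv) {
    zs <- seq(comp$center[3] - comp$semi[3], comp$center[3] + comp$semi[3], by = 0.5)
    ax_pts <- tandem_curve(spec, zs)
    for (i in seq_along(zs)) {
      f <- 1 - ((zs[i] - comp$center[3]) / comp$semi[3])^2
      if (f <= 0) next
      rx <- comp$semi[1] * sqrt(f); ry <- comp$semi[2] * sqrt(f)
      bx <- comp$center[1] + rx * cos(th) - ax_pts[i, 1]
      by <- comp$center[2] + ry * sin(th) - ax_pts[i, 2]
      max_ext <- max(max_ext, sqrt(max(bx^2 + by^2)))
      max_off <- max(max_off, sqrt((comp$center[1] - ax_pts[i, 1])^2 +
                                     (comp$center[2] - ax_pts[i, 2])^2))
    }
  }
  c(volume_cc = vol, max_ext = max_ext, max_off = max_off)
}

phantom_label <- function(spec) {
  a <- phantom_analytics(spec)
  r <- spec$rule
  as.numeric(a["max_ext"] > r$L_max || a["max_off"] > r$delta ||
               a["volume_cc"] > r$V_max)
}

# contour one ellipsoid component into planar slices with smooth radial jitter
ellipsoid_slices <- function(center, semi, slice_spacing, noise, n_vertices = 24L) {
  z0 <- center[3] - semi[3]; z1 <- center[3] + semi[3]
  zs <- seq(z0 + slice_spacing / 2, z1 - 1e-9, by = slice_spacing)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  out <- list()
  for (z in zs) {
    f <- 1 - ((z - center[3]) / semi[3])^2
    if (f <= 0.01) next
    rx <- semi[1] * sqrt(f); ry <- semi[2] * sqrt(f)
    if (noise > 0) {
      ph <- runif(2, 0, 2 * pi)
      jit <- noise * (0.6 * sin(th + ph[1]) + 0.4 * sin(2 * th + ph[2]))
    } else jit <- 0
    scale <- pmax(0.2, 1 + jit / mean(c(rx, ry)))
    v <- cbind(center[1] + rx * cos(th) * scale, center[2] + ry * sin(th) * scale)
    out[[length(out) + 1L]] <- list(z = z, vertices = v)
  }
  out
}

# bounding extents of the analytic CTV union
ctv_extents <- function(spec) {
  lo <- apply(sapply(spec$ctv, function(c_) c_$center - c_$semi), 1, min)
  hi <- apply(sapply(spec$ctv, function(c_) c_$center + c_$semi), 1, max)
  list(lo = lo, hi = hi)
}

#' Generate one synthetic structure set
#'
#' Contour stacks are sampled from the parametric surfaces at
#' `spec$slice_spacing`; the ground-truth label is computed from the
#' generating parameters (not the rasterization) via the geometric rule.
#' Uses the current RNG stream.
#'
#' @param spec a [phantom_spec()].
#' @param patient_id,insertion_id identifiers for the emitted structure set.
#' @return list with `ss` (a [structure_set()] carrying `true_label`),
#'   `label`, and the `analytics` (analytic volume/extension/offset).
#' @export
generate_phantom <- function(spec, patient_id = "phantom", insertion_id = "1") {
  ext <- ctv_extents(spec)
  # tandem polyline along the analytic centerline
  zt <- seq(0, spec$tandem_length, length.out = 9L)
  tc <- tandem_curve(spec, zt)
  tandem <- cbind(tc[, 1], tc[, 2], zt)
  structures <- list()
  add <- function(name, role, slices) {
    structures[[length(structures) + 1L]] <<- list(name = name, role = role,
                                                   slices = slices)
  }
  ctv_slices <- do.call(c, lapply(spec$ctv, function(comp)
    ellipsoid_slices(comp$center, comp$semi, spec$slice_spacing, spec$noise)))
  add("HR-CTV", "HR_CTV", ctv_slices)
  # anatomic OAR placement relative to the CTV bounding extents
  place <- list(
    bladder = function(o) c(0, ext$lo[2] - o$gap - o$semi[2],
                            mean(c(ext$lo[3], ext$hi[3]))),
    rectum = function(o) c(0, ext$hi[2] + o$gap + o$semi[2],
                           mean(c(ext$lo[3], ext$hi[3])) - 5),
    sigmoid = function(o) c(0, 10, ext$hi[3] + o$gap + o$semi[3]),
    small_bowel = function(o) c(ext$hi[1] + o$gap + o$semi[1] - 10, -5,
                                ext$hi[3] + o$gap / 2 + o$semi[3] / 2 + 10),
    large_bowel = function(o) c(ext$lo[1] - o$gap - o$semi[1] + 10, -5,
                                ext$hi[3] + o$gap / 2 + o$semi[3] / 2 + 12))
  role_of <- c(bladder = "BLADDER", rectum = "RECTUM", sigmoid = "SIGMOID",
               small_bowel = "SMALL_BOWEL", large_bowel = "LARGE_BOWEL")
  for (nm in names(spec$oars)) {
    o <- spec$oars[[nm]]
    if (is.null(o)) next
    ctr <- place[[nm]](o)
    # infeasible if the OAR body would swallow the tandem axis
    axis_xy <- tandem_curve(spec, ctr[3])
    d_axis <- sqrt(sum((ctr[1:2] - axis_xy[1, ])^2))
    if (ctr[3] > 0 && ctr[3] < spec$tandem_length &&
        d_axis < max(o$semi[1:2]) * 0.5)
      abort("phantom_error", sprintf("%s overlaps the tandem", nm))
    add(nm, role_of[[nm]],
        ellipsoid_slices(ctr, o$semi, spec$slice_spacing, spec$noise))
  }
  lab <- phantom_label(spec)
  ss <- structure_set(patient_id, insertion_id, structures, tandem,
                      true_label = lab)
  list(ss = ss, label = lab, analytics = phantom_analytics(spec))
}

#' Draw a random phantom description
#'
#' Samples CTV volume (20-120 cc), shape ratios, lateral offset and component
#' count from the generator's cohort distributions; when `target_label` is
#' given, rejection-samples until the analytic rule assigns that label.
#' Uses the current RNG stream.
#'
#' @param rule a [phantom_rule()].
#' @param target_label optional 1 (Syed) / 0 (T&O) to condition on.
#' @param noise,slice_spacing passed to [phantom_spec()].
#' @param margin named vector `c(ext =, off =, vol =)` of half-widths of an
#'   exclusion band around the rule thresholds (mm, mm, cc). Anatomies whose
#'   analytic quantities fall inside a band are rejected, keeping the classes
#'   separable relative to the ~1-2 mm contouring-jitter and voxelization
#'   uncertainty of the measured quantities; labels of band cases would not
#'   be recoverable from the observable inputs. Use zeros for an unrestricted
#'   continuum.
#' @param max_tries rejection-sampling cap.
#' @return A [phantom_spec()].
#' @export
sample_phantom_spec <- function(rule = phantom_rule(), target_label = NULL,
                                noise = 1, slice_spacing = 2.5,
                                margin = c(ext = 5, off = 2.5, vol = 10),
                                max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    n_comp <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
    vol <- runif(1, 20, 120)
    fracs <- if (n_comp == 1) 1 else {
      f <- c(runif(1, 0.55, 0.8), runif(n_comp - 1))
      c(f[1], (1 - f[1]) * f[-1] / sum(f[-1]))
    }
    ry <- runif(1, 0.7, 1.2); rz <- runif(1, 0.9, 1.6)
    off_x <- runif(1, 0, 18) * sample(c(-1, 1), 1)
    off_y <- runif(1, 0, 6) * sample(c(-1, 1), 1)
    zc <- runif(1, 24, 34)
    comps <- list()
    for (j in seq_len(n_comp)) {
      axx <- (3 * fracs[j] * vol * 1000 / (4 * pi * ry * rz))^(1 / 3)
      semi <- c(axx, axx * ry, axx * rz)
      if (j == 1L) {
        center <- c(off_x, off_y, zc)
      } else {
        # stack the 2nd component inferior and the 3rd superior to the main
        # body, keeping the union within a physiologic SI span
        prev <- comps[[1]]
        dz <- prev$semi[3] + semi[3] + 0.5
        if (j == 3L) dz <- dz + comps[[2]]$semi[3] * 0  # superior side
        zdir <- if (j == 2L) -1 else 1
        center <- c(off_x + runif(1, -6, 6), off_y + runif(1, -4, 4),
                    prev$center[3] + zdir * dz)
      }
      comps[[j]] <- list(center = center, semi = semi)
    }
    spec <- phantom_spec(comps, rule = rule, noise = noise,
                         slice_spacing = slice_spacing)
    ext <- ctv_extents(spec)
    # physiologic feasibility: pelvic CTVs do not span > ~9 cm SI or reach
    # > ~5.5 cm laterally from the canal
    if ((ext$hi[3] - ext$lo[3]) > 90 ||
        max(abs(c(ext$lo[1:2], ext$hi[1:2]))) > 55) next
    a <- phantom_analytics(spec)
    in_band <- abs(a[["max_ext"]] - rule$L_max) < margin[["ext"]] ||
      abs(a[["max_off"]] - rule$delta) < margin[["off"]] ||
      abs(a[["volume_cc"]] - rule$V_max) < margin[["vol"]]
    if (in_band) next
    if (is.null(target_label) || phantom_label(spec) == target_label)
      return(spec)
  }
  abort("phantom_error", "could not sample a phantom matching the target label")
}

# small within-patient perturbation of a phantom spec (inter-insertion
# anatomy change <= ~3 mm at the surface)
perturb_phantom_spec <- function(spec) {
  spec$ctv <- lapply(spec$ctv, function(comp) {
    comp$semi <- comp$semi * runif(3, 0.96, 1.04)
    comp$center <- comp$center + c(runif(2, -2, 2), runif(1, -1, 1))
    comp
  })
  spec
}

#' Generate a synthetic cohort
#'
#' Each patient gets a base anatomy whose class is drawn with probability
#' `syed_fraction` (rejection-sampled against the rule), and 1-5 insertions
#' that are small perturbations of it — so grouped cross-validation leakage
#' is meaningful to test. Reproducible under `seed`.
#'
#' @param n_patients number of patients (>= 2).
#' @param syed_fraction probability a patient's base anatomy is a Syed case.
#' @param insertions_per_patient either a single integer (fixed count) or a
#'   probability vector over counts `1..length(...)`.
#' @param rule a [phantom_rule()].
#' @param noise contour jitter amplitude, mm.
#' @param slice_spacing contour slice spacing, mm.
#' @param label_flip_noise probability an insertion's label is flipped, to
#'   emulate physician variability (default 0: noiseless labels).
#' @param margin threshold exclusion band, see [sample_phantom_spec()].
#' @param seed integer seed.
#' @return list with `structure_sets` (list of [structure_set()]) and
#'   `manifest` (patient_id, insertion_id, label, generating analytics).
#' @export
generate_cohort <- function(n_patients = 60L, syed_fraction = 0.3,
                            insertions_per_patient = c(0.35, 0.35, 0.2, 0.1),
                            rule = phantom_rule(), noise = 1,
                            slice_spacing = 2.5, label_flip_noise = 0,
                            margin = c(ext = 5, off = 2.5, vol = 10),
                            seed = 1L) {
  stopifnot(n_patients >= 2L, syed_fraction > 0, syed_fraction < 1)
  set.seed(seed)
  sets <- list()
  manifest <- NULL
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    target <- as.numeric(runif(1) < syed_fraction)
    base <- sample_phantom_spec(rule = rule, target_label = target,
                                noise = noise, slice_spacing = slice_spacing,
                                margin = margin)
    n_ins <- if (length(insertions_per_patient) == 1L) insertions_per_patient
    else sample(seq_along(insertions_per_patient), 1,
                prob = insertions_per_patient)
    for (ins in seq_len(n_ins)) {
      spc <- if (ins == 1L) base else perturb_phantom_spec(base)
      ph <- generate_phantom(spc, patient_id = pid,
                             insertion_id = sprintf("%s-I%d", pid, ins))
      lab <- ph$label
      if (label_flip_noise > 0 && runif(1) < label_flip_noise) {
        lab <- 1 - lab
        ph$ss$true_label <- lab
      }
      sets[[length(sets) + 1L]] <- ph$ss
      manifest <- rbind(manifest, data.frame(
        patient_id = pid, insertion_id = ph$ss$insertion_id, label = lab,
        volume_cc = ph$analytics["volume_cc"], max_ext = ph$analytics["max_ext"],
        max_off = ph$analytics["max_off"], row.names = NULL))
    }
  }
  list(structure_sets = sets, manifest = manifest)
}

#' Write a cohort to disk (contour files + manifest CSV)
#'
#' @param cohort from [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ss in cohort$structure_sets) {
    write_structure_set(ss, file.path(dir, paste0(ss$insertion_id, ".json")))
  }
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Encode a cohort into training records
#'
#' Rasterizes and encodes every insertion on a tandem-centered grid.
#'
#' @param cohort from [generate_cohort()] (or a list of structure sets with
#'   `true_label`s).
#' @param shape,spacing encoding grid geometry.
#' @param mode `"FULL"` or `"MASK_ONLY"`.
#' @return list of insertion records suitable for [train_network()].
#' @export
prepare_training_records <- function(cohort, shape = c(48L, 48L, 48L),
                                     spacing = 3, mode = c("FULL", "MASK_ONLY")) {
  mode <- match.arg(mode)
  sets <- if (!is.null(cohort$structure_sets)) cohort$structure_sets else cohort
  lapply(sets, function(ss) {
    ip <- suppressWarnings(prepare_input(ss, shape = shape, spacing = spacing,
                                         mode = mode))
    list(patient_id = ss$patient_id, insertion_id = ss$insertion_id,
         x = ip$x, y = as.numeric(ss$true_label))
  })
}
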