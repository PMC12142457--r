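# Structure sets: named planar contour stacks plus the digitized central
# tandem, in physical mm coordinates. This mirrors what treatment-planning
# systems store in an RT structure set, reduced to what applicator selection
# needs.

#' Structure roles recognized by the pipeline
#' @export
structure_roles <- function() {
  c("HR_CTV", "IR_CTV", "BLADDER", "RECTUM", "SIGMOID",
    "SMALL_BOWEL", "LARGE_BOWEL")
}

oar_roles <- function() c("BLADDER", "RECTUM", "SIGMOID", "SMALL_BOWEL", "LARGE_BOWEL")

#' Default alias table mapping institution-style contour names to roles
#'
#' Used by [read_structure_set()] to resolve free-text structure names.
#' Matching is case-insensitive after stripping non-alphanumerics.
#' @return Named character vector, `name -> role`.
#' @export
default_alias_table <- function() {
  c("hrctv" = "HR_CTV", "ctvhr" = "HR_CTV", "hrctv1" = "HR_CTV",
    "irctv" = "IR_CTV", "ctvir" = "IR_CTV",
    "bladder" = "BLADDER", "vessie" = "BLADDER",
    "rectum" = "RECTUM",
    "sigmoid" = "SIGMOID", "sigmoidcolon" = "SIGMOID",
    "smallbowel" = "SMALL_BOWEL", "bowelsmall" = "SMALL_BOWEL",
    "largebowel" = "LARGE_BOWEL", "bowellarge" = "LARGE_BOWEL", "bowel" = "SMALL_BOWEL")
}

normalize_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Assemble and validate a structure set
#'
#' @param patient_id,insertion_id opaque identifier strings.
#' @param structures list of structures, each
#'   `list(name =, role =, slices = list(list(z =, vertices = <n x 2 (x, y) mm>)))`.
#'   Every polygon must be closed (first vertex not repeated) with at least 3
#'   vertices.
#' @param tandem n x 3 matrix of tandem points, columns `(x, y, z)` mm, with
#'   strictly monotone z (superior--inferior ordering). At least 2 points.
#' @param true_label optional ground-truth applicator label, `1` (Syed) or
#'   `0` (T&O).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(patient_id, insertion_id, structures, tandem,
                          true_label = NA) {
  roles <- vapply(structures, function(s) s$role, character(1))
  bad <- setdiff(roles, structure_roles())
  if (length(bad))
    abort("input_error", paste("unknown structure role(s):", paste(bad, collapse = ", ")))
  if (!"HR_CTV" %in% roles)
    abort("missing_target", "structure set has no HR_CTV")
  if (is.null(tandem) || !is.matrix(tandem) || nrow(tandem) < 2L)
    abort("missing_tandem", "tandem polyline absent or has fewer than 2 points")
  if (ncol(tandem) != 3L || any(!is.finite(tandem)))
    abort("malformed_tandem", "tandem must be an n x 3 finite matrix (x, y, z)")
  dz <- diff(tandem[, 3])
  if (!(all(dz > 0) || all(dz < 0)))
    abort("malformed_tandem",
          "tandem points must be strictly ordered along the superior-inferior axis")
  if (all(dz < 0)) tandem <- tandem[rev(seq_len(nrow(tandem))), , drop = FALSE]
  for (s in structures) {
    for (sl in s$slices) {
      v <- sl$vertices
      if (!is.matrix(v) || nrow(v) < 3L)
        abort("degenerate_contour",
              sprintf("structure '%s': polygon with < 3 vertices", s$name))
      if (any(!is.finite(v)) || !is.finite(sl$z))
        abort("input_error", sprintf("structure '%s': non-finite coordinates", s$name))
    }
  }
  if (!is.na(true_label) && !true_label %in% c(0, 1))
    abort("input_error", "true_label must be 0 (T&O), 1 (Syed) or NA")
  structure(list(patient_id = as.character(patient_id),
                 insertion_id = as.character(insertion_id),
                 structures = structures, tandem = tandem,
                 true_label = true_label),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  roles <- vapply(x$structures, function(s) s$role, character(1))
  cat(sprintf("<structure_set> patient %s insertion %s: %s; tandem %d pts; label %s\n",
              x$patient_id, x$insertion_id, paste(roles, collapse = ", "),
              nrow(x$tandem),
              if (is.na(x$true_label)) "NA" else if (x$true_label == 1) "Syed" else "T&O"))
  invisible(x)
}

ss_get_role <- function(ss, role) {
  hit <- Filter(function(s) s$role == role, ss$structures)
  if (!length(hit)) return(NULL)
  # several contours may share a role; concatenate slices
  list(role = role, slices = do.call(c, lapply(hit, function(s) s$slices)))
}

#' Read a structure set from the structured-text contour format
#'
#' The on-disk format is a single JSON document holding the patient and
#' insertion identifiers, the tandem polyline, an optional ground-truth
#' label, and one record per structure with its name and planar contours
#' (z plus (x, y) vertex list, mm). [write_structure_set()] emits it. Export
#' contours from a DICOM-RT structure set to this format with any DICOM
#' toolchain; binary DICOM parsing is outside this package's scope.
#'
#' Structure names are resolved to roles through `alias_table` (see
#' [default_alias_table()]); names carrying an explicit recognized `role`
#' field bypass the table. Unrecognized structures are skipped with a
#' warning.
#'
#' @param path file path.
#' @param alias_table named character vector mapping normalized structure
#'   names to roles.
#' @return A [structure_set()].
#' @export
read_structure_set <- function(path, alias_table = default_alias_table()) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  structures <- list()
  for (rec in doc$structures) {
    role <- rec$role
    if (is.null(role) || !role %in% structure_roles()) {
      key <- normalize_name(rec$name %||% "")
      role <- unname(alias_table[key])
      if (is.na(role) || is.null(role)) {
        warn_log(sprintf("skipping unrecognized structure '%s'", rec$name %||% "?"))
        next
      }
    }
    slices <- lapply(rec$slices, function(sl) {
      v <- do.call(rbind, lapply(sl$vertices, function(p) as.numeric(unlist(p))))
      list(z = as.numeric(sl$z), vertices = v)
    })
    structures[[length(structures) + 1L]] <-
      list(name = rec$name %||% role, role = role, slices = slices)
  }
  tandem <- if (!is.null(doc$tandem))
    do.call(rbind, lapply(doc$tandem, function(p) as.numeric(unlist(p))))
  if (is.null(tandem))
    abort("missing_tandem", sprintf("no tandem polyline in '%s'", path))
  lab <- doc$true_label
  structure_set(doc$patient_id %||% "unknown", doc$insertion_id %||% "unknown",
                structures, tandem,
                true_label = if (is.null(lab)) NA else as.numeric(lab))
}

#' Write a structure set to the structured-text contour format
#'
#' @param ss a [structure_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_set <- function(ss, path) {
  doc <- list(
    patient_id = ss$patient_id,
    insertion_id = ss$insertion_id,
    true_label = if (is.na(ss$true_label)) NULL else ss$true_label,
    tandem = apply(ss$tandem, 1, function(p) as.numeric(p), simplify = FALSE),
    structures = lapply(ss$structures, function(s) {
      list(name = s$name, role = s$role,
           slices = lapply(s$slices, function(sl) {
             list(z = sl$z,
                  vertices = apply(sl$vertices, 1, as.numeric, simplify = FALSE))
           }))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- tandem axis helpers -----------------------------------------------------

# (x, y) position of the tandem axis at height z. Inside the polyline's z
# range the polyline is interpolated linearly; beyond its endpoints a straight
# line least-squares fitted to all polyline points is extended.
tandem_axis_at <- function(tandem, z) {
  zs <- tandem[, 3]
  n <- nrow(tandem)
  fit_x <- stats::lm.fit(cbind(1, zs), tandem[, 1])$coefficients
  fit_y <- stats::lm.fit(cbind(1, zs), tandem[, 2])$coefficients
  out <- matrix(NA_real_, length(z), 2)
  inside <- z >= zs[1] & z <= zs[n]
  if (any(inside)) {
    out[inside, 1] <- stats::approx(zs, tandem[, 1], xout = z[inside])$y
    out[inside, 2] <- stats::approx(zs, tandem[, 2], xout = z[inside])$y
  }
  if (any(!inside)) {
    out[!inside, 1] <- fit_x[1] + fit_x[2] * z[!inside]
    out[!inside, 2] <- fit_y[1] + fit_y[2] * z[!inside]
  }
  colnames(out) <- c("x", "y")
  out
}

tandem_centroid <- function(tandem) {
  # mean of points along the polyline weighted by segment length, so the
  # centroid is insensitive to digitization density
  if (nrow(tandem) == 2L) return(colMeans(tandem))
  seg <- diff(tandem)
  len <- sqrt(rowSums(seg^2))
  mid <- (tandem[-1, , drop = FALSE] + tandem[-nrow(tandem), , drop = FALSE]) / 2
  if (sum(len) == 0) return(colMeans(tandem))
  colSums(mid * len) / sum(len)
}
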