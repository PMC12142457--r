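# Independent brute-force oracles and small geometric fixtures. These
# reimplement the geometric primitives directly from their definitions (plain
# R, no shared code with the package internals) so the fast kernels can be
# checked against them.

# even-odd ray-casting point-in-polygon
oracle_pip <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# closed-form point-to-segment distance
oracle_seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.xmin)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

# min over segments of a polyline
oracle_polyline_dist <- function(p, line) {
  min(vapply(seq_len(nrow(line) - 1), function(s)
    oracle_seg_dist(p, line[s, ], line[s + 1, ]), numeric(1)))
}

# --- fixtures ----------------------------------------------------------------

square_slices <- function(side = 10, z = 0, center = c(0, 0)) {
  half <- side / 2
  v <- cbind(center[1] + c(-half, half, half, -half),
             center[2] + c(-half, -half, half, half))
  list(list(z = z, vertices = v))
}

circle_slices <- function(radius, z = 0, center = c(0, 0), n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(list(z = z, vertices = cbind(center[1] + radius * cos(th),
                                    center[2] + radius * sin(th))))
}

# stack of circular contours approximating a z-aligned cylinder
cylinder_slices <- function(radius, z0, z1, dz = 2, center = c(0, 0), n = 96) {
  do.call(c, lapply(seq(z0, z1, by = dz), function(z)
    circle_slices(radius, z = z, center = center, n = n)))
}

straight_tandem <- function(length = 60, x = 0, y = 0) {
  cbind(rep(x, 2), rep(y, 2), c(0, length))
}

# minimal valid structure set: square HR-CTV plus a straight tandem
tiny_structure_set <- function(label = 1) {
  structure_set("p1", "i1",
                list(list(name = "HRCTV", role = "HR_CTV",
                          slices = square_slices(20, z = 30))),
                straight_tandem(), true_label = label)
}

# a small shared cohort + encoded records, built once per test run
tiny_cohort_env <- new.env()
tiny_cohort <- function() {
  if (is.null(tiny_cohort_env$coh)) {
    tiny_cohort_env$coh <- generate_cohort(n_patients = 14, syed_fraction = 0.4,
                                           insertions_per_patient = 2, seed = 42)
  }
  tiny_cohort_env$coh
}
tiny_records <- function(mode = "FULL") {
  key <- paste0("recs_", mode)
  if (is.null(tiny_cohort_env[[key]])) {
    tiny_cohort_env[[key]] <- prepare_training_records(
      tiny_cohort(), shape = c(24L, 24L, 24L), spacing = 5, mode = mode)
  }
  tiny_cohort_env[[key]]
}
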