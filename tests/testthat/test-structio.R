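# Structure-set I/O, rasterization, tandem tube and label composition.

test_that("structure_set validates its invariants", {
  ss <- tiny_structure_set()
  expect_s3_class(ss, "structure_set")
  # missing target
  expect_error(structure_set("p", "i", list(), straight_tandem()),
               class = "brachysel_missing_target")
  # missing / malformed tandem
  ctv <- list(list(name = "HRCTV", role = "HR_CTV", slices = square_slices()))
  expect_error(structure_set("p", "i", ctv, NULL),
               class = "brachysel_missing_tandem")
  expect_error(structure_set("p", "i", ctv, matrix(c(0, 0, 0), 1, 3)),
               class = "brachysel_missing_tandem")
  zigzag <- cbind(0, 0, c(0, 10, 5))
  expect_error(structure_set("p", "i", ctv, zigzag),
               class = "brachysel_malformed_tandem")
  # inferior-first ordering is normalized, not rejected
  down <- structure_set("p", "i", ctv, cbind(0, 0, c(60, 0)))
  expect_true(all(diff(down$tandem[, 3]) > 0))
  # degenerate polygon
  bad <- list(list(name = "HRCTV", role = "HR_CTV",
                   slices = list(list(z = 0, vertices = matrix(0, 2, 2)))))
  expect_error(structure_set("p", "i", bad, straight_tandem()),
               class = "brachysel_degenerate_contour")
})

test_that("contour files round-trip through the text format", {
  ss <- tiny_structure_set()
  path <- withr::local_tempfile(fileext = ".json")
  write_structure_set(ss, path)
  back <- read_structure_set(path)
  expect_equal(back$patient_id, ss$patient_id)
  expect_equal(back$tandem, ss$tandem, ignore_attr = TRUE, tolerance = 1e-12)
  expect_length(back$structures, 1L)
  expect_equal(back$structures[[1]]$slices[[1]]$vertices,
               ss$structures[[1]]$slices[[1]]$vertices,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$true_label, 1)

  # a phantom-generated set round-trips too
  set.seed(7)
  ph <- generate_phantom(sample_phantom_spec())
  p2 <- withr::local_tempfile(fileext = ".json")
  write_structure_set(ph$ss, p2)
  b2 <- read_structure_set(p2)
  expect_equal(length(b2$structures), length(ph$ss$structures))
  expect_equal(b2$structures[[1]]$slices[[3]]$vertices,
               ph$ss$structures[[1]]$slices[[3]]$vertices,
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(b2$true_label, ph$label)
})

test_that("alias resolution maps names to roles and skips unknowns", {
  ss <- tiny_structure_set()
  ss$structures[[1]]$name <- "HR-CTV 1"
  ss$structures[[1]]$role <- NULL
  path <- withr::local_tempfile(fileext = ".json")
  # write manually to drop the role field
  doc <- jsonlite::read_json(write_structure_set(tiny_structure_set(), path))
  doc$structures[[1]]$role <- NULL
  doc$structures[[1]]$name <- "hrCTV"
  doc$structures[[2]] <- doc$structures[[1]]
  doc$structures[[2]]$name <- "Aorta"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_warning(back <- read_structure_set(path), "unrecognized")
  expect_equal(vapply(back$structures, `[[`, character(1), "role"), "HR_CTV")
})

test_that("file with CTV but no tandem raises MissingTandem", {
  path <- withr::local_tempfile(fileext = ".json")
  write_structure_set(tiny_structure_set(), path)
  doc <- jsonlite::read_json(path)
  doc$tandem <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_structure_set(path), class = "brachysel_missing_tandem")
})

test_that("rasterization matches analytic counts on simple shapes", {
  # 10x10 mm square on a 2 mm grid with centers at 1,3,5,7,9 -> 25 voxels
  g <- grid_spec(shape = c(1L, 5L, 5L), spacing = 2, origin = c(0, 1, 1))
  m <- rasterize_structure(square_slices(10, z = 0, center = c(5, 5)), g)
  expect_equal(sum(m), 25L)

  # circle r = 20: in-plane area within 5% of pi r^2
  g2 <- grid_spec(shape = c(1L, 30L, 30L), spacing = 2, origin = c(0, -29, -29))
  m2 <- rasterize_structure(circle_slices(20), g2)
  expect_lt(abs(sum(m2) * 4 - pi * 400) / (pi * 400), 0.05)

  expect_error(rasterize_structure(list(list(z = 0, vertices = matrix(0, 2, 2))), g),
               class = "brachysel_degenerate_contour")
})

test_that("rasterization equals the even-odd oracle at every voxel center", {
  set.seed(101)
  g <- grid_spec(shape = c(1L, 16L, 16L), spacing = 2, origin = c(0, -15, -15))
  ax <- brachysel:::grid_axes(g)
  for (rep in 1:25) {
    nv <- sample(3:12, 1)
    # star-shaped random polygon (simple by construction)
    th <- sort(runif(nv, 0, 2 * pi))
    r <- runif(nv, 3, 14)
    v <- cbind(r * cos(th), r * sin(th))
    m <- rasterize_structure(list(list(z = 0, vertices = v)), g)
    for (j in seq_along(ax$y)) {
      for (k in seq_along(ax$x)) {
        expect_identical(m[1, j, k],
                         oracle_pip(ax$x[k], ax$y[j], v[, 1], v[, 2]))
      }
    }
  }
})

test_that("nested contours at one z behave as holes", {
  g <- grid_spec(shape = c(1L, 15L, 15L), spacing = 2, origin = c(0, -14, -14))
  outer <- square_slices(24, z = 0)[[1]]
  inner <- square_slices(8, z = 0)[[1]]
  m <- rasterize_structure(list(outer, inner), g)
  expect_false(m[1, 8, 8])       # center voxel is inside the hole
  expect_true(m[1, 2, 8])        # annulus voxel
})

test_that("tandem tube matches per-voxel brute-force distance", {
  g <- grid_spec(shape = c(10L, 11L, 11L), spacing = 2, origin = c(0, -10, -10))
  t1 <- straight_tandem(length = 18)
  m <- tandem_tube(t1, g, diameter = 5)
  ax <- brachysel:::grid_axes(g)
  # straight vertical line through voxel centers: in-plane distance <= 2.5
  for (j in seq_along(ax$y)) for (k in seq_along(ax$x)) {
    expect_equal(m[5, j, k], sqrt(ax$y[j]^2 + ax$x[k]^2) <= 2.5)
  }
  # diameter 0: only voxels exactly on the line
  m0 <- tandem_tube(t1, g, diameter = 0)
  expect_equal(sum(m0), 10L)
  expect_true(all(which(m0, arr.ind = TRUE)[, 2:3] == 6))
  expect_error(tandem_tube(matrix(c(0, 0, 0), 1, 3), g),
               class = "brachysel_malformed_tandem")
})

test_that("bent-polyline tube membership equals the exhaustive oracle", {
  set.seed(33)
  g <- grid_spec(shape = c(8L, 8L, 8L), spacing = 3, origin = c(-10, -10, -10))
  ax <- brachysel:::grid_axes(g)
  for (rep in 1:6) {
    np <- sample(2:6, 1)
    line <- cbind(runif(np, -8, 8), runif(np, -8, 8), sort(runif(np, -10, 12)))
    line <- line[!duplicated(line[, 3]), , drop = FALSE]
    if (nrow(line) < 2) next
    m <- tandem_tube(line, g, diameter = 7)
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      d <- oracle_polyline_dist(c(ax$x[k], ax$y[j], ax$z[i]), line)
      expect_identical(m[i, j, k], d <= 3.5 + 1e-12)
    }
  }
})

test_that("label composition follows tandem > CTV > OAR precedence", {
  g <- grid_spec(shape = c(4L, 4L, 4L), spacing = 2)
  ctv <- array(FALSE, g$shape); ctv[1:3, 1:3, 1:3] <- TRUE
  tan <- array(FALSE, g$shape); tan[2, 2, 2] <- TRUE
  oar <- array(FALSE, g$shape); oar[3:4, 3:4, 3:4] <- TRUE
  lv <- compose_label_volume(ctv, tan, list(bladder = oar), g)
  expect_equal(lv$values[2, 2, 2], 2L)              # tandem over CTV
  expect_equal(lv$values[3, 3, 3], 1L)              # CTV over OAR
  expect_equal(lv$values[4, 4, 4], 3L)
  expect_equal(lv$values[1, 4, 4], 0L)
  # permuting OARs never changes the output
  oar2 <- array(FALSE, g$shape); oar2[4, 1, 1] <- TRUE
  a <- compose_label_volume(ctv, tan, list(a = oar, b = oar2), g)
  b <- compose_label_volume(ctv, tan, list(b = oar2, a = oar), g)
  expect_identical(a$values, b$values)
  # idempotent
  c2 <- compose_label_volume(ctv, tan, list(a = oar, b = oar2), g)
  expect_identical(a$values, c2$values)
  expect_error(compose_label_volume(array(FALSE, g$shape), tan, list(), g),
               class = "brachysel_missing_target")
})

test_that("labelled voxel count is subadditive, with equality iff disjoint", {
  g <- grid_spec(shape = c(6L, 6L, 6L), spacing = 2)
  set.seed(5)
  for (rep in 1:10) {
    ctv <- array(runif(216) < 0.3, g$shape)
    ctv[1, 1, 1] <- TRUE
    tan <- array(runif(216) < 0.1, g$shape); tan[2, 1, 1] <- TRUE
    oar <- array(runif(216) < 0.2, g$shape)
    lv <- compose_label_volume(ctv, tan, list(o = oar), g)
    n_lab <- sum(lv$values != 0)
    n_sum <- sum(ctv) + sum(tan) + sum(oar)
    expect_lte(n_lab, n_sum)
    disjoint <- !any((ctv & tan) | (ctv & oar) | (tan & oar))
    expect_identical(n_lab == n_sum, disjoint)
  }
})

test_that("resampling is identity on matching grids and tracks volume at 1 mm", {
  g <- grid_spec(shape = c(8L, 8L, 8L), spacing = 2)
  m <- array(FALSE, g$shape); m[3:6, 3:6, 3:6] <- TRUE
  expect_identical(resample_and_crop(m, g, g), m)

  # 1 mm native cuboid 12 x 12 x 12 mm resampled to 2 mm
  gn <- grid_spec(shape = c(20L, 20L, 20L), spacing = 1)
  mn <- array(FALSE, gn$shape); mn[5:16, 5:16, 5:16] <- TRUE
  gt <- grid_spec(shape = c(10L, 10L, 10L), spacing = 2, origin = c(0, 0, 0))
  mt <- resample_and_crop(mn, gn, gt)
  vol_native <- sum(mn) * 1
  vol_target <- sum(mt) * 8
  expect_lt(abs(vol_target - vol_native) / vol_native, 0.35) # one-voxel shell
  # structure fully outside the window -> empty + warning
  gfar <- grid_spec(shape = c(5L, 5L, 5L), spacing = 2, origin = c(100, 100, 100))
  expect_warning(far <- resample_and_crop(mn, gn, gfar), "outside")
  expect_false(any(far))
})
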