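# Handcrafted geometric features and the classical-ML benchmark components.

test_that("ctv_volume counts voxels in cc", {
  g <- grid_spec(shape = c(10L, 10L, 10L), spacing = 2)
  m <- array(FALSE, g$shape)
  m[seq_len(250)] <- TRUE
  expect_equal(ctv_volume(m, g), 2)      # 250 x 8 mm^3 = 2 cc
  expect_error(ctv_volume(array(FALSE, g$shape), g),
               class = "brachysel_missing_target")
})

test_that("rasterized ellipsoid volume is within 5% of the analytic value", {
  spec <- phantom_spec(list(list(center = c(0, 0, 30), semi = c(20, 15, 15))),
                       noise = 0, slice_spacing = 2)
  ph <- generate_phantom(spec)
  ras <- suppressWarnings(rasterize_structure_set(ph$ss, shape = c(48, 48, 48),
                                                  spacing = 2))
  v <- ctv_volume(ras$masks$hr_ctv, ras$grid)
  v_true <- 4 / 3 * pi * 20 * 15 * 15 / 1000
  expect_lt(abs(v - v_true) / v_true, 0.05)
})

test_that("lateral extension and offset recover cylinder geometry", {
  tan_line <- straight_tandem(60)
  # coaxial cylinder radius 15
  ss <- structure_set("p", "i",
                      list(list(name = "HRCTV", role = "HR_CTV",
                                slices = cylinder_slices(15, 20, 40))),
                      tan_line)
  ras <- suppressWarnings(rasterize_structure_set(ss, shape = c(40, 40, 40),
                                                  spacing = 2))
  le <- lateral_extension(ras$masks$hr_ctv, tan_line, ras$grid)
  expect_lt(abs(le["avg"] - 15), sqrt(2) * 2)
  expect_lt(abs(le["max"] - 15), sqrt(2) * 2)
  co <- com_offset(ras$masks$hr_ctv, tan_line, ras$grid)
  expect_lt(co[["avg"]], 1.2)           # half a voxel
  expect_lt(co[["max"]], 1.5)
  # the same cylinder shifted 10 mm laterally
  ss2 <- structure_set("p", "i",
                       list(list(name = "HRCTV", role = "HR_CTV",
                                 slices = cylinder_slices(15, 20, 40,
                                                          center = c(10, 0)))),
                       tan_line)
  ras2 <- suppressWarnings(rasterize_structure_set(ss2, shape = c(40, 40, 40),
                                                   spacing = 2))
  le2 <- lateral_extension(ras2$masks$hr_ctv, tan_line, ras2$grid)
  expect_lt(abs(le2[["max"]] - 25), sqrt(2) * 2)
  co2 <- com_offset(ras2$masks$hr_ctv, tan_line, ras2$grid)
  expect_lt(abs(co2[["avg"]] - 10), 1.2)
  expect_lt(abs(co2[["max"]] - 10), 1.5)
})

test_that("per-slice extension and offset equal a brute-force oracle", {
  set.seed(41)
  g <- grid_spec(shape = c(12L, 14L, 14L), spacing = 3, origin = c(0, -20, -20))
  tan_line <- cbind(c(1, -1, 2), c(0, 1, -1), c(-5, 15, 40))
  mask <- array(runif(prod(g$shape)) < 0.15, g$shape)
  mask[3, 4, 5] <- TRUE
  ax <- brachysel:::grid_axes(g)
  le <- lateral_extension(mask, tan_line, g)
  co <- com_offset(mask, tan_line, g)
  exts <- offs <- c()
  for (i in seq_along(ax$z)) {
    sl <- mask[i, , ]
    if (!any(sl)) next
    # oracle: interpolate/extrapolate the axis exactly as documented
    zq <- ax$z[i]
    zs <- tan_line[, 3]
    if (zq >= zs[1] && zq <= zs[3]) {
      axy <- c(approx(zs, tan_line[, 1], zq)$y, approx(zs, tan_line[, 2], zq)$y)
    } else {
      cx <- coef(lm(tan_line[, 1] ~ zs)); cy <- coef(lm(tan_line[, 2] ~ zs))
      axy <- c(cx[1] + cx[2] * zq, cy[1] + cy[2] * zq)
    }
    jk <- which(sl, arr.ind = TRUE)
    pys <- ax$y[jk[, 1]]; pxs <- ax$x[jk[, 2]]
    exts <- c(exts, max(sqrt((pxs - axy[1])^2 + (pys - axy[2])^2)))
    offs <- c(offs, sqrt((mean(pxs) - axy[1])^2 + (mean(pys) - axy[2])^2))
  }
  expect_equal(unname(le), c(mean(exts), max(exts)), tolerance = 1e-10)
  expect_equal(unname(co), c(mean(offs), max(offs)), tolerance = 1e-10)
})

test_that("nearest-2cc distances follow grid geometry and the brute-force oracle", {
  g <- grid_spec(shape = c(10L, 10L, 10L), spacing = 2)
  ctv <- array(FALSE, g$shape); ctv[3:6, 3:6, 3:6] <- TRUE
  # abutting OAR sharing a face: nearest centers 2 mm apart
  oar <- array(FALSE, g$shape); oar[3:6, 7, 3:6] <- TRUE
  d <- nearest_2cc_distances(oar, ctv, g)
  expect_equal(unname(d["min"]), 2)
  expect_true(all(d >= 0))
  expect_lte(d[["min"]], d[["avg"]]); expect_lte(d[["avg"]], d[["max"]])
  # an OAR of <= 250 voxels (2 cc at 2 mm) uses all its voxels
  expect_equal(unname(d["max"]), max(brachysel:::cpp_min_point_distance(
    brachysel:::voxel_coords(g, oar),
    brachysel:::voxel_coords(g, brachysel:::cpp_boundary_mask(ctv)))))

  # random masks against a sort-all-distances oracle
  set.seed(43)
  for (rep in 1:8) {
    ctv <- array(runif(1000) < 0.2, g$shape); ctv[5, 5, 5] <- TRUE
    oar <- array(runif(1000) < 0.4, g$shape); oar[1, 1, 1] <- TRUE
    got <- nearest_2cc_distances(oar, ctv, g)
    # independent boundary: voxel in ctv with a 6-neighbour outside
    is_b <- function(i, j, k) {
      nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                  c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
      any(apply(nb, 1, function(p) {
        if (any(p < 1 | p > 10)) TRUE else !ctv[p[1], p[2], p[3]]
      }))
    }
    cidx <- which(ctv, arr.ind = TRUE)
    bsel <- apply(cidx, 1, function(p) is_b(p[1], p[2], p[3]))
    ax <- brachysel:::grid_axes(g)
    bxyz <- cbind(ax$x[cidx[bsel, 3]], ax$y[cidx[bsel, 2]], ax$z[cidx[bsel, 1]])
    oidx <- which(oar, arr.ind = TRUE)
    dall <- vapply(seq_len(nrow(oidx)), function(r) {
      p <- c(ax$x[oidx[r, 3]], ax$y[oidx[r, 2]], ax$z[oidx[r, 1]])
      if (ctv[oidx[r, 1], oidx[r, 2], oidx[r, 3]]) return(0)
      min(sqrt(rowSums(sweep(bxyz, 2, p)^2)))
    }, numeric(1))
    sel <- sort(dall)[seq_len(min(length(dall), 250))]
    expect_equal(unname(got), c(max(sel), min(sel), mean(sel)), tolerance = 1e-9)
  }
})

test_that("the feature vector has the fixed 20-column schema", {
  set.seed(47)
  ph <- generate_phantom(sample_phantom_spec())
  f <- extract_features(ph$ss, shape = c(40, 40, 40), spacing = 3)
  expect_length(f, 20L)
  expect_identical(names(f), feature_names())
  # triples are ordered max >= avg >= min
  for (oar in tolower(c("BLADDER", "RECTUM", "SIGMOID", "SMALL_BOWEL", "LARGE_BOWEL"))) {
    expect_gte(f[[paste0(oar, "_d2cc_max")]], f[[paste0(oar, "_d2cc_avg")]])
    expect_gte(f[[paste0(oar, "_d2cc_avg")]], f[[paste0(oar, "_d2cc_min")]])
  }
  expect_gte(f[["lat_ext_max"]], f[["lat_ext_avg"]])
  # missing OAR -> sentinel triple with a warning
  ss <- ph$ss
  ss$structures <- Filter(function(s) s$role != "BLADDER", ss$structures)
  expect_warning(f2 <- extract_features(ss, shape = c(40, 40, 40), spacing = 3),
                 "bladder")
  expect_equal(unname(f2["bladder_d2cc_max"]), missing_oar_sentinel)
  expect_equal(unname(f2["bladder_d2cc_min"]), missing_oar_sentinel)
})

test_that("a mirror-symmetric phantom has (near) zero asymmetry offset", {
  spec <- phantom_spec(list(list(center = c(0, 0, 30), semi = c(18, 15, 16))),
                       tandem_bow = 0, noise = 0)
  ph <- generate_phantom(spec)
  f <- extract_features(ph$ss, shape = c(48, 48, 48), spacing = 2)
  expect_lt(f[["com_offset_avg"]], 1)
  expect_lt(f[["com_offset_max"]], 1)
})

test_that("features are invariant to rotating the scene about a straight tandem", {
  spec <- phantom_spec(list(list(center = c(9, 3, 30), semi = c(16, 13, 14))),
                       tandem_bow = 0, noise = 0)
  ph <- generate_phantom(spec)
  rot <- function(ss, th) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    ss$structures <- lapply(ss$structures, function(s) {
      s$slices <- lapply(s$slices, function(sl) {
        sl$vertices <- sl$vertices %*% t(R)
        sl
      })
      s
    })
    ss
  }
  f1 <- suppressWarnings(extract_features(ph$ss, shape = c(48, 48, 48), spacing = 2))
  f2 <- suppressWarnings(extract_features(rot(ph$ss, pi / 3),
                                          shape = c(48, 48, 48), spacing = 2))
  for (nm in c("ctv_volume_cc", "lat_ext_avg", "lat_ext_max",
               "com_offset_avg", "com_offset_max")) {
    expect_lt(abs(f1[[nm]] - f2[[nm]]) / max(abs(f1[[nm]]), 1), 0.12)
  }
})

test_that("translating an OAR away weakly increases its distance triple", {
  g <- grid_spec(shape = c(16L, 16L, 16L), spacing = 2)
  ctv <- array(FALSE, g$shape); ctv[6:10, 6:10, 6:10] <- TRUE
  prev <- c(-Inf, -Inf, -Inf)
  for (shift in 0:3) {
    oar <- array(FALSE, g$shape)
    oar[6:9, (12 + shift):min(16, 14 + shift), 6:9] <- TRUE
    d <- nearest_2cc_distances(oar, ctv, g)
    expect_true(all(d >= prev - 1e-9))
    prev <- d
  }
})

test_that("ANOVA-F ranking matches lm and handles edge cases", {
  set.seed(51)
  y <- rep(c(0, 1), each = 12)
  X <- cbind(sig = y + rnorm(24, sd = 0.05),
             noise1 = rnorm(24), noise2 = rnorm(24), const = rep(2, 24))
  expect_warning(rk <- rank_features(X, y), "constant")
  expect_equal(rk$order[1], 1L)
  expect_equal(rk$f_scores[[4]], 0)
  # F equals the classical one-way ANOVA statistic
  f_lm <- anova(lm(X[, 1] ~ factor(y)))$`F value`[1]
  expect_equal(rk$f_scores[[1]], f_lm, tolerance = 1e-10)
  # hand-computed toy: groups {1,2,3} and {4,5,6}
  toy <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  rk2 <- rank_features(toy, c(0, 0, 0, 1, 1, 1))
  expect_equal(rk2$f_scores[[1]], (13.5 / 1) / (4 / 4))
  expect_error(rank_features(X, rep(1, 24)), class = "brachysel_class_missing")
})

test_that("SMOTE balances classes with convex-combination synthetics", {
  set.seed(53)
  X <- rbind(matrix(rnorm(200), 100, 2),
             matrix(rnorm(80, mean = 4), 40, 2))
  y <- c(rep(0, 100), rep(1, 40))
  sm <- smote_oversample(X, y, k = 5)
  expect_equal(as.integer(table(sm$y)), c(100L, 100L))
  synth <- sm$X[141:200, , drop = FALSE]
  Xm <- X[y == 1, ]
  # every synthetic point lies on a segment between two minority points
  for (i in seq_len(nrow(synth))) {
    s <- synth[i, ]
    on_seg <- FALSE
    for (a in seq_len(40)) {
      for (b in seq_len(40)) {
        if (a == b) next
        ab <- Xm[b, ] - Xm[a, ]
        t <- sum((s - Xm[a, ]) * ab) / sum(ab^2)
        if (t > -1e-9 && t < 1 + 1e-9 &&
            sqrt(sum((s - (Xm[a, ] + t * ab))^2)) < 1e-8) {
          on_seg <- TRUE
          break
        }
      }
      if (on_seg) break
    }
    expect_true(on_seg)
  }
  expect_error(smote_oversample(X[1:101, ], y[1:101]),
               class = "brachysel_smote_error")
})

test_that("soft voting averages the model probabilities", {
  v <- soft_vote(matrix(c(0.9, 0.8, 0.2, 0.4), 1, 4))
  expect_equal(v$score, 0.575)
  expect_identical(v$label, "SYED")
  # four identical models equal any single model
  m <- matrix(rep(c(0.3, 0.7), each = 4), 2, 4, byrow = TRUE)
  expect_equal(soft_vote(m)$score, c(0.3, 0.7))
})

test_that("the ensemble separates an easy synthetic problem", {
  set.seed(57)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n), n, 2), matrix(rnorm(2 * n, mean = 3), n, 2))
  X <- cbind(X, matrix(rnorm(4 * 2 * n), 2 * n, 4))   # distractors
  colnames(X) <- paste0("f", 1:6)
  y <- rep(c(0, 1), each = n)
  tr <- c(1:45, 61:105); te <- setdiff(1:(2 * n), tr)
  bm <- ml_benchmark(X[tr, ], y[tr], X[te, ], n_top = 2)
  expect_gte(mean((bm$vote$score >= 0.5) == (y[te] == 1)), 0.9)
  expect_identical(dim(bm$prob), c(length(te), 4L))
  expect_error(ml_benchmark(X[1:45, ], y[1:45], X[te, ], n_top = 2),
               class = "brachysel_class_missing")
})
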