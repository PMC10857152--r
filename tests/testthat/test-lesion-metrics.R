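test_that("lesion models derive volume and centroid from the grid", {
  les <- cube_lesion(c(5, 5, 5), c(15, 15, 15), c(20, 20, 20),
                     origin = c(-10, -10, -10))
  expect_equal(les$volume, 11^3 / 1000, tolerance = 1e-9)
  # centroid of voxel centres: indices 4..14 (0-based), origin -10
  expect_equal(les$centroid, c(-1, -1, -1), tolerance = 1e-9)

  spaced <- lesion_model(array(TRUE, c(2, 3, 4)),
                         spacing = c(0.5, 1, 2), origin = c(1, 2, 3))
  expect_equal(spaced$volume, 24 * 1 / 1000, tolerance = 1e-12)

  expect_error(lesion_model(array(FALSE, c(3, 3, 3))), "empty")
  expect_error(lesion_model(matrix(TRUE, 2, 2)), "3-D")
})

test_that("DSC matches direct voxel counting and is symmetric", {
  a <- cube_lesion(c(1, 1, 1), c(10, 10, 10), c(20, 10, 10))
  b <- cube_lesion(c(6, 1, 1), c(15, 10, 10), c(20, 10, 10))
  expect_equal(dsc(a, b), 2 * 500 / (1000 + 1000))
  expect_equal(dsc(a, b), dsc(b, a))
  expect_equal(dsc(a, a), 1)

  disjoint <- cube_lesion(c(12, 1, 1), c(20, 10, 10), c(20, 10, 10))
  expect_equal(dsc(a, disjoint), 0)

  other_grid <- cube_lesion(c(1, 1, 1), c(10, 10, 10), c(20, 10, 10),
                            origin = c(5, 0, 0))
  expect_error(dsc(a, other_grid), "same voxel grid")
})

test_that("transform_lesion resamples onto the ground-truth grid", {
  gt <- cube_lesion(c(8, 8, 8), c(17, 17, 17), c(25, 25, 25))

  tm_id <- transform_lesion(gt, rigid_transform())
  expect_identical(tm_id$mask, gt$mask)
  expect_equal(dsc(gt, tm_id), 1)

  # one-voxel translation: index-shift oracle
  tm_shift <- transform_lesion(gt, rigid_transform(translation = c(1, 0, 0)))
  shifted <- array(FALSE, dim(gt$mask))
  shifted[2:25, , ] <- gt$mask[1:24, , ]
  expect_identical(tm_shift$mask, shifted)

  # 90 deg rotation about the superior axis through the centroid of a
  # symmetric cube maps the cube onto itself
  gt_cube <- cube_lesion(c(8, 8, 8), c(17, 17, 17), c(25, 25, 25),
                         origin = -c(11.5, 11.5, 11.5))
  expect_equal(gt_cube$centroid, c(0, 0, 0))
  rot <- oracle_rotation(c(0, 0, 1), 90)
  tm_rot <- transform_lesion(gt_cube, rigid_transform(rot))
  expect_identical(tm_rot$mask, gt_cube$mask)
})

test_that("directed HD95 takes the maximum of the smallest 95% of distances", {
  # 100 isolated ground-truth voxels, each paired with one transformed-model
  # voxel: 95 partners at 1 mm, 5 partners at 10 mm, pairs 25 mm apart so
  # nearest neighbours never cross pairs
  nx <- 99 * 25 + 11
  gt_m <- array(FALSE, c(nx, 3, 1))
  tm_m <- array(FALSE, c(nx, 3, 1))
  for (i in 0:99) {
    gt_m[i * 25 + 1, 1, 1] <- TRUE
    off <- if (i < 95) 1 else 10
    tm_m[i * 25 + 1 + off, 1, 1] <- TRUE
  }
  gt <- lesion_model(gt_m)
  tm <- lesion_model(tm_m)
  expect_equal(hd95(gt, tm, mode = "directed", rule = "lower"), 1.0)
  # the linear interpolation rule instead lands between the order statistics
  expect_equal(hd95(gt, tm, mode = "directed", rule = "linear"),
               1 + 0.05 * 9, tolerance = 1e-9)
  expect_equal(hd95(gt, gt), 0)
})

test_that("HD95 of a translated slab is the translation within a voxel", {
  slab <- cube_lesion(c(3, 3, 3), c(38, 38, 8), c(42, 42, 12))
  tm <- transform_lesion(slab, rigid_transform(translation = c(2, 0, 0)))
  h <- hd95(slab, tm)
  expect_lt(abs(h - 2), 1 + 1e-9)
  expect_gt(h, 0)
  # symmetric variant dominates both directed ones
  expect_gte(hd95(slab, tm, mode = "symmetric"), h)
})

test_that("HD95 agrees with a brute-force nearest-neighbour recomputation", {
  set.seed(50)
  gt <- cube_lesion(c(4, 4, 4), c(12, 14, 10), c(20, 20, 16))
  tm <- transform_lesion(gt, rigid_transform(oracle_rotation(c(0, 0, 1), 8),
                                             c(1.5, -1, 0.5)))
  surf_pts <- function(les) {
    m <- les$mask
    d <- dim(m)
    keep <- matrix(NA_real_, 0, 3)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (!m[i, j, k]) next
      nb <- c(if (i > 1) m[i - 1, j, k] else FALSE,
              if (i < d[1]) m[i + 1, j, k] else FALSE,
              if (j > 1) m[i, j - 1, k] else FALSE,
              if (j < d[2]) m[i, j + 1, k] else FALSE,
              if (k > 1) m[i, j, k - 1] else FALSE,
              if (k < d[3]) m[i, j, k + 1] else FALSE)
      if (!all(nb)) keep <- rbind(keep, les$origin + (c(i, j, k) - 1) *
                                    les$spacing)
    }
    keep
  }
  g <- surf_pts(gt)
  t2 <- surf_pts(tm)
  dists <- apply(g, 1, function(p) min(sqrt(colSums((t(t2) - p)^2))))
  dists <- sort(dists)
  expected <- dists[floor(0.95 * length(dists))]
  expect_equal(hd95(gt, tm), expected, tolerance = 1e-9)
})

test_that("lesion depth is the tangent-sphere radius to the skin mesh", {
  sphere <- ellipsoid_mesh(c(80, 80, 80), n_lat = 48, n_lon = 96)
  expect_equal(lesion_depth(c(0, 0, 0), sphere), 8, tolerance = 0.05)
  d <- lesion_depth(c(30, 0, 0), sphere)
  expect_equal(d, 5, tolerance = 0.05)
  # brute-force vertex distance is an upper bound on the face distance
  vert_min <- min(sqrt(rowSums(sweep(sphere$vertices, 2,
                                     c(30, 0, 0))^2))) / 10
  expect_lte(d, vert_min + 1e-12)
  # a centroid sitting on the mesh surface has zero depth
  expect_equal(lesion_depth(sphere$vertices[10, ], sphere), 0,
               tolerance = 1e-9)

  degen <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                        matrix(c(1, 2, 3), 1))
  expect_error(lesion_depth(c(5, 5, 5), degen), "zero-area")
})

test_that("point-to-triangle distance beats vertex-only distance on coarse meshes", {
  coarse <- ellipsoid_mesh(c(80, 80, 80), n_lat = 6, n_lon = 8)
  exact <- min(point_triangle_distances(c(0, 0, 0), coarse))
  vertex_only <- min(sqrt(rowSums(coarse$vertices^2)))
  expect_lt(exact, vertex_only)  # faces cut inside the vertex sphere
})

test_that("the L2 norm reports centroid distance from the origin in cm", {
  expect_equal(l2_norm(c(0, 0, 0)), 0)
  expect_equal(l2_norm(c(30, 40, 0)), 5)
  expect_equal(l2_norm(c(10, 10, 10)), sqrt(300) / 10, tolerance = 1e-12)
})

test_that("DSC grows with lesion volume under a fixed misregistration", {
  # a family of similar-shaped lesions spanning the cohort's volume range,
  # all displaced by the same rigid error: larger lesions keep more overlap
  set.seed(51)
  t_err <- rigid_transform(oracle_rotation(c(0.2, 0.5, 1), 1.2),
                           c(1.8, -1.4, 1.2))
  volumes <- seq(4, 44, length.out = 21)
  dscs <- vapply(volumes, function(v) {
    r <- (3 * v * 1000 / (4 * pi))^(1 / 3)
    n <- ceiling(2 * r) + 13
    ax <- seq_len(n) - (n + 1) / 2
    mask <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= r^2
    gt <- lesion_model(mask, origin = -c(1, 1, 1) * (n - 1) / 2)
    dsc(gt, transform_lesion(gt, t_err))
  }, 1)
  expect_gt(suppressWarnings(cor(volumes, dscs, method = "spearman")), 0)
  expect_true(all(dscs > 0 & dscs < 1))
})

test_that("evaluate_lesions returns one row per lesion with all metrics", {
  case <- generate_case(seed = 9, n_lesions = 2)
  tbl <- evaluate_lesions(case)
  expect_equal(nrow(tbl), 2)
  expect_true(all(c("volume_cm3", "depth_cm", "l2_norm_cm", "dsc",
                    "hd95_mm") %in% names(tbl)))
  expect_true(all(tbl$dsc >= 0 & tbl$dsc <= 1))
  expect_true(all(tbl$hd95_mm >= 0))
  expect_true(all(tbl$depth_cm > 0))
  expect_error(evaluate_lesions(list(lesions = list())), "no lesions")
})
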