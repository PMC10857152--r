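test_that("FLE and TRE are per-marker displacement vectors with norms", {
  c_pts <- tetra_points()
  v_same <- fiducial_set(fid_matrix(c_pts), role = "V")
  expect_true(all(compute_fle(v_same, c_pts)$magnitude == 0))

  one_c <- fiducial_set(tibble::tibble(label = 1, x = 0, y = 0, z = 0))
  one_v <- fiducial_set(tibble::tibble(label = 1, x = 1, y = 2, z = 2),
                        role = "V")
  expect_equal(compute_fle(one_v, one_c)$magnitude, 3)

  p_shift <- fiducial_set(sweep(fid_matrix(c_pts), 2, c(0, 0, 3), `+`),
                          role = "P")
  tre <- compute_tre(p_shift, c_pts)
  expect_equal(tre$magnitude, rep(3, 4))
  expect_identical(attr(tre, "kind"), "TRE")

  # norm oracle: elementwise recomputation on seeded offsets
  set.seed(40)
  offs <- matrix(rnorm(21), ncol = 3)
  c7 <- random_points(7)
  v7 <- fiducial_set(fid_matrix(c7) + offs, role = "V")
  fle <- compute_fle(v7, c7)
  expect_equal(fle$magnitude, sqrt(rowSums(offs^2)), tolerance = 1e-12)
  expect_equal(cbind(fle$dx, fle$dy, fle$dz), unname(offs),
               tolerance = 1e-12)
})

test_that("TRE matches the closed form of a known misregistration", {
  set.seed(41)
  c_pts <- random_points(7)
  rot <- oracle_rotation(c(1, -1, 2), 2)
  trans <- c(1.5, -0.5, 2)
  p_pts <- apply_rigid_to_set(c_pts, rot, trans, role = "P")
  tre <- compute_tre(p_pts, c_pts)
  expected <- sqrt(rowSums(
    (fid_matrix(c_pts) %*% t(rot) +
       rep(1, 7) %o% trans - fid_matrix(c_pts))^2))
  expect_equal(tre$magnitude, unname(expected), tolerance = 1e-12)
})

test_that("FRE vanishes for an exact rigid motion and equals fit residuals", {
  set.seed(42)
  c_pts <- random_points(6)
  p_exact <- apply_rigid_to_set(c_pts, oracle_rotation(c(0, 1, 0), 12),
                                c(3, 3, -3), role = "P")
  fit <- fit_rigid(c_pts, p_exact)
  expect_lt(max(compute_fre(c_pts, p_exact, fit)$magnitude), 1e-9)

  pm <- fid_matrix(c_pts) + matrix(rnorm(18, 0, 1.2), ncol = 3)
  p_noisy <- fiducial_set(pm, role = "P")
  fit <- fit_rigid(c_pts, p_noisy)
  fre <- compute_fre(c_pts, p_noisy, fit)
  res_norm <- sqrt(fit$residuals$dx^2 + fit$residuals$dy^2 +
                     fit$residuals$dz^2)
  expect_equal(fre$magnitude, res_norm, tolerance = 1e-12)

  other <- random_points(6, role = "P")
  other$label <- other$label + 10
  expect_error(compute_fre(c_pts, fiducial_set(other, role = "P"), fit),
               "label")
})

test_that("a non-rigid stretch leaves the residual the optimizer predicts", {
  # two point pairs 10 mm apart stretched to 12 mm, thickened into a
  # non-collinear configuration symmetric about the stretch axis
  c_pts <- fiducial_set(rbind(c(0, 0, 0), c(10, 0, 0),
                              c(0, 10, 0), c(10, 10, 0)))
  pm <- rbind(c(0, 0, 0), c(12, 0, 0), c(0, 10, 0), c(12, 10, 0))
  p_pts <- fiducial_set(pm, role = "P")
  fit <- fit_rigid(c_pts, p_pts)
  oracle <- brute_force_rigid(fid_matrix(c_pts), pm)
  expect_lt(max(abs(fit$matrix - oracle$matrix)), 1e-6)
  # the optimum splits the 2 mm excess equally: residual 1 mm per point
  fre <- compute_fre(c_pts, p_pts, fit)
  expect_equal(fre$magnitude, rep(1, 4), tolerance = 1e-9)
})

test_that("the Frobenius norm measures transform size entrywise", {
  expect_equal(compute_fn(rigid_transform()), 0)
  expect_equal(compute_fn(rigid_transform(translation = c(3, 4, 0))), 5)
  rot180 <- rigid_transform(oracle_rotation(c(0, 0, 1), 180))
  expect_equal(compute_fn(rot180), sqrt(8), tolerance = 1e-12)

  dec <- compute_fn(rigid_transform(oracle_rotation(c(0, 0, 1), 180),
                                    c(3, 4, 0)), decompose = TRUE)
  expect_equal(dec$fn, sqrt(8 + 25), tolerance = 1e-12)
  expect_equal(dec$fn_rotation, sqrt(8), tolerance = 1e-12)
  expect_equal(dec$fn_translation, 5)
})

test_that("per-case summaries use mean and sample SD of the magnitudes", {
  c_pts <- fiducial_set(rbind(c(0, 0, 0), c(60, 0, 0), c(0, 60, 0)))
  v_pts <- fiducial_set(fid_matrix(c_pts) + cbind(c(1, 2, 3), 0, 0),
                        role = "V")
  case <- list(case_id = "t", position = "supine",
               fiducials_C = c_pts, fiducials_V = v_pts,
               fiducials_P = fiducial_set(fid_matrix(c_pts), role = "P"))
  s <- summarize_case(case)
  expect_equal(s$mean_fle, 2)
  expect_equal(s$sd_fle, 1)  # sample SD of {1,2,3}
  expect_equal(s$mean_tre, 0)
  expect_equal(s$mean_fre, 0, tolerance = 1e-9)
  expect_equal(s$fn, 0, tolerance = 1e-9)
  expect_identical(s$measurement_order, "V_before_P")

  expect_error(summarize_case(list(case_id = "x", fiducials_C = c_pts)),
               "missing point sets")
})

test_that("summaries match a spreadsheet-style recomputation on a seeded case", {
  case <- generate_case(seed = 77)
  s <- summarize_case(case)
  cm <- fid_matrix(case$fiducials_C)
  vm <- fid_matrix(case$fiducials_V)
  pm <- fid_matrix(case$fiducials_P)
  fle_mag <- sqrt(rowSums((vm - cm)^2))
  tre_mag <- sqrt(rowSums((pm - cm)^2))
  expect_equal(s$mean_fle, mean(fle_mag), tolerance = 1e-12)
  expect_equal(s$sd_fle, sd(fle_mag), tolerance = 1e-12)
  expect_equal(s$mean_tre, mean(tre_mag), tolerance = 1e-12)
  expect_equal(s$sd_tre, sd(tre_mag), tolerance = 1e-12)
})

test_that("with rigid-only error the optimal fit removes all of it", {
  # zero probe noise: FRE collapses to ~0 while TRE stays positive
  for (seed in c(5, 6, 7)) {
    case <- generate_case(seed = seed,
                          noise = noise_model(sigma_probe = 0))
    s <- summarize_case(case)
    expect_lt(s$mean_fre, 1e-9)
    expect_gt(s$mean_tre, 0)
    expect_lte(s$mean_fre, s$mean_tre)
  }
})

test_that("mean FLE increases with probe noise", {
  mean_fle_at <- function(sigma) {
    mags <- unlist(lapply(1:40, function(i) {
      cs <- generate_case(seed = i,
                          noise = noise_model(sigma_probe = sigma,
                                              rot_sigma = 0,
                                              trans_sigma = 0))
      compute_fle(cs$fiducials_V, cs$fiducials_C)$magnitude
    }))
    mean(mags)
  }
  levels <- vapply(c(0.5, 1.2, 2.5), mean_fle_at, 1)
  expect_true(all(diff(levels) > 0))
})
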