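# shared fixtures and independent oracles, built in code at test time

# four non-coplanar points with head-like coordinates
tetra_points <- function() {
  fiducial_set(rbind(c(10, 80, 20), c(-60, 30, 40),
                     c(55, -20, 60), c(0, 10, -70)))
}

# n random points in a 160 mm box, as a fiducial set
random_points <- function(n, role = "C") {
  fiducial_set(matrix(runif(3 * n, -80, 80), ncol = 3), role = role)
}

# independent Rodrigues formula (distinct from the package's internal one)
oracle_rotation <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  cos(a) * diag(3) + sin(a) *
    matrix(c(0, uz, -uy, -uz, 0, ux, uy, -ux, 0), 3) +
    (1 - cos(a)) * (u %o% u)
}

apply_rigid_to_set <- function(fs, rotation, translation, role = NULL) {
  m <- fid_matrix(fs) %*% t(rotation)
  m <- sweep(m, 2, translation, `+`)
  fiducial_set(tibble::tibble(label = fs$label, x = m[, 1], y = m[, 2],
                              z = m[, 3]),
               frame = fid_frame(fs), units = fid_units(fs),
               role = role %||% fid_role(fs))
}

# brute-force rigid least squares: numerical minimization over a
# rotation-vector + translation parameterization, multi-start BFGS
brute_force_rigid <- function(cm, pm) {
  rotvec_to_matrix <- function(v) {
    angle <- sqrt(sum(v^2))
    if (angle < 1e-12) return(diag(3))
    oracle_rotation(v / angle, angle * 180 / pi)
  }
  obj <- function(par) {
    r <- rotvec_to_matrix(par[1:3])
    pred <- cm %*% t(r)
    pred <- sweep(pred, 2, par[4:6], `+`)
    sum((pred - pm)^2)
  }
  starts <- list(rep(0, 6),
                 c(0.2, -0.1, 0.15, 0, 0, 0),
                 c(-0.3, 0.25, -0.2, 5, -5, 5))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-16))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-16))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish to high precision with Levenberg-Marquardt on the residuals
  resid_vec <- function(par) {
    r <- rotvec_to_matrix(par[1:3])
    pred <- sweep(cm %*% t(r), 2, par[4:6], `+`)
    as.numeric(pred - pm)
  }
  pol <- suppressWarnings(minpack.lm::nls.lm(
    best$par, fn = resid_vec,
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 500)))
  par <- if (sum(resid_vec(pol$par)^2) <= best$value) pol$par else best$par
  # final Gauss-Newton steps with a central-difference Jacobian
  for (iter in 1:25) {
    r <- resid_vec(par)
    jac <- vapply(1:6, function(k) {
      h <- 1e-6
      e <- numeric(6); e[k] <- h
      (resid_vec(par + e) - resid_vec(par - e)) / (2 * h)
    }, numeric(length(r)))
    step <- tryCatch(solve(crossprod(jac), -crossprod(jac, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    cand <- par + as.numeric(step)
    if (sum(resid_vec(cand)^2) > sum(r^2) + 1e-12) break
    par <- cand
    if (max(abs(step)) < 1e-12) break
  }
  m <- diag(4)
  m[1:3, 1:3] <- rotvec_to_matrix(par[1:3])
  m[1:3, 4] <- par[4:6]
  list(matrix = m, value = obj(par))
}

# axis-aligned cuboid mask helpers (1 mm grid unless stated)
cube_lesion <- function(from, to, dims, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  m <- array(FALSE, dims)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  lesion_model(m, spacing = spacing, origin = origin)
}
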