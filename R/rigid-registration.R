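#' Least-squares rigid registration of two ordered point sets
#'
#' Fits the rigid transform (rotation + translation, no scaling, no
#' reflection) that maps the ground-truth marker centroids `C` onto the
#' perceived physical markers `P`, minimizing the sum of squared residuals
#' `sum_i ||R C_i + t - P_i||^2`. Correspondence is strictly by marker
#' label order; no point matching is attempted. The solution is the
#' classical closed form: demean both sets, take the SVD of the
#' cross-covariance, and correct the sign of the smallest singular
#' direction so that `det(R) = +1` (a proper rotation even when the
#' unconstrained optimum would be a reflection).
#'
#' @param c_set Ground-truth fiducial set (role `"C"`), RICS mm.
#' @param p_set Perceived physical fiducial set (role `"P"`), same labels
#'   in the same order, RICS mm.
#'
#' @return A `rigid_fit` object with elements `rotation` (3x3), `translation`
#'   (length 3, mm), `matrix` (4x4 homogeneous), `residuals` (tibble of
#'   per-marker residual vectors `R C_i + t - P_i`, mm) and `rms_residual`.
#'   `tidy()` returns the per-marker residuals with magnitudes; `glance()`
#'   a one-row fit summary.
#' @examples
#' c_pts <- fiducial_set(cbind(c(0, 80, 0, 0), c(0, 0, 90, 0), c(0, 0, 0, 70)))
#' p_pts <- fiducial_set(fid_matrix(c_pts) + rep(c(5, -3, 2), each = 4),
#'                       role = "P")
#' fit <- fit_rigid(c_pts, p_pts)
#' fit$translation   # (5, -3, 2)
#' glance(fit)
#' @export
fit_rigid <- function(c_set, p_set) {
  stopifnot(inherits(c_set, "fiducial_set"), inherits(p_set, "fiducial_set"))
  if (nrow(c_set) < 3 || nrow(p_set) < 3) {
    abort("rigid registration needs at least 3 point pairs")
  }
  check_matched_sets(c_set, p_set, "ground-truth (C)", "physical (P)")
  cm <- fid_matrix(c_set)
  pm <- fid_matrix(p_set)
  c_bar <- colMeans(cm)
  p_bar <- colMeans(pm)
  cc <- sweep(cm, 2, c_bar)
  pc <- sweep(pm, 2, p_bar)

  # the source configuration must span a plane, otherwise the rotation
  # about the degenerate axis is unidentifiable
  sv_c <- svd(cc)$d
  if (sv_c[2] <= 1e-8 * max(sv_c[1], 1)) {
    abort("degenerate fiducial configuration: points are collinear")
  }

  h <- t(cc) %*% pc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(p_bar - rot %*% c_bar)

  m <- diag(4)
  m[1:3, 1:3] <- rot
  m[1:3, 4] <- trans

  res <- transform_points(m, cm) - pm
  dimnames(res) <- NULL
  residuals <- tibble(label = c_set$label,
                      dx = res[, 1], dy = res[, 2], dz = res[, 3])

  structure(
    list(rotation = rot, translation = trans, matrix = m,
         residuals = residuals,
         rms_residual = sqrt(mean(rowSums(res^2))),
         n = nrow(c_set)),
    class = "rigid_fit")
}

#' Build a rigid_fit directly from a rotation and translation
#'
#' Used by the phantom generator to store the ground-truth misregistration
#' in the same shape as a fitted transform, and handy in tests.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 translation (mm).
#' @return A `rigid_fit` with empty residuals.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-9 ||
      det(rotation) < 0) {
    abort("rotation must be a proper orthogonal 3x3 matrix")
  }
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  structure(
    list(rotation = rotation, translation = as.numeric(translation),
         matrix = m,
         residuals = tibble(label = integer(), dx = double(),
                            dy = double(), dz = double()),
         rms_residual = NA_real_, n = 0L),
    class = "rigid_fit")
}

#' @export
print.rigid_fit <- function(x, ...) {
  cat(sprintf("<rigid_fit> %d point pairs, RMS residual %.4g mm\n",
              x$n, x$rms_residual))
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation (mm):", round(x$translation, 4), "\n")
  invisible(x)
}

#' @rdname fit_rigid
#' @param x A `rigid_fit`.
#' @param ... Unused.
#' @method tidy rigid_fit
#' @export
tidy.rigid_fit <- function(x, ...) {
  dplyr::mutate(x$residuals,
                magnitude = sqrt(.data$dx^2 + .data$dy^2 + .data$dz^2))
}

#' @rdname fit_rigid
#' @method glance rigid_fit
#' @export
glance.rigid_fit <- function(x, ...) {
  tr <- sum(diag(x$rotation))
  angle <- acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
  tibble(n = x$n,
         rms_residual = x$rms_residual,
         fn = compute_fn(x),
         rotation_angle_deg = angle,
         translation_norm = sqrt(sum(x$translation^2)))
}
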