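#' Frame transforms between the image and virtual coordinate systems
#'
#' A `frame_transform` is a 4x4 homogeneous matrix tagged with its source and
#' target frames and units. The transform chain mirrors how a holographic
#' display platform consumes medical images: the reference image coordinate
#' system (RICS; RAS, millimetres) is mapped by the forward engineering
#' matrix (FEM) into an intermediate virtual frame (IVCS; centimetres,
#' rotated to suit the surgical position), a handedness conversion matrix
#' (HCM) then flips the third axis into the left-handed virtual frame (VCS),
#' and the reverse engineering matrix (REM) -- the exact inverse of the FEM
#' -- brings measurements back into the analysis frame (ACS), which is
#' identified with RICS (right-handed, mm).
#'
#' @param matrix A 4x4 homogeneous matrix (bottom row `0 0 0 1`).
#' @param source_frame,target_frame Frame tags (`"RICS"`, `"IVCS"`, `"VCS"`,
#'   `"ACS"`).
#' @param unit_in,unit_out Length units of the source and target frames.
#' @param position Optional surgical-position label the transform was built
#'   for.
#'
#' @return A `frame_transform` object.
#' @seealso [make_fem()], [make_rem()], [make_hcm()], [apply_transform()]
#' @export
frame_transform <- function(matrix, source_frame, target_frame,
                            unit_in = "mm", unit_out = "mm",
                            position = NULL) {
  frames <- c("RICS", "IVCS", "VCS", "ACS")
  source_frame <- match.arg(source_frame, frames)
  target_frame <- match.arg(target_frame, frames)
  unit_in <- match.arg(unit_in, c("mm", "cm"))
  unit_out <- match.arg(unit_out, c("mm", "cm"))
  if (!is.matrix(matrix) || !identical(dim(matrix), c(4L, 4L))) {
    abort("a frame transform needs a 4x4 matrix")
  }
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-12) {
    abort("bottom row of a homogeneous transform must be (0, 0, 0, 1)")
  }
  if (abs(det(matrix)) < 1e-12) abort("transform matrix is not invertible")
  structure(
    list(matrix = matrix, source_frame = source_frame,
         target_frame = target_frame, unit_in = unit_in,
         unit_out = unit_out, position = position),
    class = "frame_transform")
}

#' @export
print.frame_transform <- function(x, ...) {
  cat(sprintf("<frame_transform> %s [%s] -> %s [%s]%s\n",
              x$source_frame, x$unit_in, x$target_frame, x$unit_out,
              if (is.null(x$position)) "" else paste0(" (", x$position, ")")))
  print(round(x$matrix, 6))
  invisible(x)
}

surgical_positions <- function() {
  c("supine", "prone", "left_lateral", "right_lateral")
}

# rotation about the superior (z, cranio-caudal) axis, angle in degrees
rot_superior <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), nrow = 3, byrow = TRUE)
}

position_angle <- function(position, lateral_sign) {
  position <- match.arg(position, surgical_positions())
  s <- switch(lateral_sign, left_positive = 1, right_positive = -1,
              abort("lateral_sign must be 'left_positive' or 'right_positive'"))
  switch(position,
         supine = 0, prone = 180,
         left_lateral = 90 * s, right_lateral = -90 * s)
}

#' Forward, reverse and handedness conversion matrices
#'
#' `make_fem()` builds the forward engineering matrix mapping the reference
#' image frame (RICS, mm) into the intermediate virtual frame (IVCS, cm):
#' a rotation about the superior (vertical) axis that depends on the
#' surgical position -- 0 deg supine, 180 deg prone, +/-90 deg lateral --
#' composed with a uniform 0.1 scale (mm to cm). `make_rem()` is its exact
#' matrix inverse, mapping IVCS (cm) back to the analysis frame (ACS, mm,
#' identical to RICS). `make_hcm()` is the handedness conversion
#' `diag(1, 1, -1, 1)` that negates the superior axis, taking the
#' right-handed IVCS into the left-handed VCS.
#'
#' The side-to-angle assignment for lateral positions is a convention, not a
#' physical fact; it is exposed through `lateral_sign` (default: left-lateral
#' rotates by +90 deg).
#'
#' @param position Surgical position: `"supine"`, `"prone"`,
#'   `"left_lateral"` or `"right_lateral"`.
#' @param lateral_sign `"left_positive"` (left-lateral -> +90 deg, default)
#'   or `"right_positive"` (the mirrored convention).
#'
#' @return A [frame_transform()].
#' @examples
#' fem <- make_fem("prone")
#' fem$matrix %*% c(100, 50, -20, 1)  # (-10, -5, -2, 1) in cm
#' @export
make_fem <- function(position, lateral_sign = "left_positive") {
  angle <- position_angle(position, lateral_sign)
  m <- diag(4)
  m[1:3, 1:3] <- 0.1 * rot_superior(angle)
  frame_transform(m, "RICS", "IVCS", unit_in = "mm", unit_out = "cm",
                  position = position)
}

#' @rdname make_fem
#' @export
make_rem <- function(position, lateral_sign = "left_positive") {
  fem <- make_fem(position, lateral_sign)
  frame_transform(solve(fem$matrix), "IVCS", "ACS",
                  unit_in = "cm", unit_out = "mm", position = position)
}

#' @rdname make_fem
#' @export
make_hcm <- function() {
  frame_transform(diag(c(1, 1, -1, 1)), "IVCS", "VCS",
                  unit_in = "cm", unit_out = "cm")
}

#' Invert a frame transform
#'
#' @param transform A [frame_transform()].
#' @return The inverse transform, with source/target frames and units
#'   swapped.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "frame_transform"))
  frame_transform(solve(transform$matrix),
                  source_frame = transform$target_frame,
                  target_frame = transform$source_frame,
                  unit_in = transform$unit_out,
                  unit_out = transform$unit_in,
                  position = transform$position)
}

#' Apply a frame transform to a fiducial set
#'
#' Transforms every point and re-tags the result with the transform's target
#' frame and unit. The input's frame and unit tags must match the
#' transform's declared source; silent unit coercion is never performed.
#'
#' @param points A [fiducial_set()].
#' @param transform A [frame_transform()].
#' @return A [fiducial_set()] in the target frame, same labels and order.
#' @examples
#' pts <- fiducial_set(data.frame(label = 1, x = 100, y = 50, z = -20))
#' apply_transform(pts, make_fem("supine"))
#' @export
apply_transform <- function(points, transform) {
  stopifnot(inherits(points, "fiducial_set"),
            inherits(transform, "frame_transform"))
  if (!identical(fid_frame(points), transform$source_frame) ||
      !identical(fid_units(points), transform$unit_in)) {
    abort(sprintf(
      "cannot apply %s [%s] -> %s [%s] transform to points in frame %s [%s]",
      transform$source_frame, transform$unit_in,
      transform$target_frame, transform$unit_out,
      fid_frame(points), fid_units(points)))
  }
  xyz <- transform_points(transform$matrix, fid_matrix(points))
  fiducial_set(tibble(label = points$label,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
               frame = transform$target_frame,
               units = transform$unit_out,
               role = fid_role(points))
}

# apply a 4x4 homogeneous matrix to an n x 3 coordinate matrix
transform_points <- function(m4, xyz) {
  stopifnot(ncol(xyz) == 3)
  out <- xyz %*% t(m4[1:3, 1:3])
  out <- sweep(out, 2, m4[1:3, 4], `+`)
  colnames(out) <- c("x", "y", "z")
  out
}
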