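#' Ordered, labelled fiducial point sets
#'
#' A `fiducial_set` is a tibble with columns `label`, `x`, `y`, `z` carrying
#' three coordinate-frame tags as attributes: the frame (`"RICS"`, `"IVCS"`,
#' `"VCS"` or `"ACS"`), the length unit (`"mm"` or `"cm"`), and the role of
#' the set in the accuracy analysis: `"C"` (ground-truth marker centroids
#' from the reference image), `"V"` (marker positions perceived on the
#' virtual overlay), or `"P"` (marker positions perceived on the physical
#' phantom). Coordinates are RAS (right-anterior-superior) when the frame is
#' right-handed. Point order is meaningful: correspondence between two sets
#' is by position after checking that labels agree.
#'
#' @param points A data frame with columns `label`, `x`, `y`, `z` (or a
#'   numeric matrix with three columns, in which case labels `1:n` are
#'   assigned).
#' @param frame Coordinate frame tag.
#' @param units Length unit of the coordinates.
#' @param role Which point set this is in the analysis.
#'
#' @return A `fiducial_set` tibble.
#' @examples
#' fiducial_set(data.frame(label = 1:3, x = c(0, 10, 0),
#'                         y = c(0, 0, 10), z = 0))
#' @export
fiducial_set <- function(points,
                         frame = c("RICS", "IVCS", "VCS", "ACS"),
                         units = c("mm", "cm"),
                         role = c("C", "V", "P")) {
  frame <- match.arg(frame)
  units <- match.arg(units)
  role <- match.arg(role)
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    points <- tibble(label = seq_len(nrow(points)),
                     x = points[, 1], y = points[, 2], z = points[, 3])
  }
  points <- as_tibble(points)
  required <- c("label", "x", "y", "z")
  missing <- setdiff(required, names(points))
  if (length(missing) > 0) {
    abort(paste0("fiducial points need columns: ",
                 paste(missing, collapse = ", ")))
  }
  points <- points[required]
  if (nrow(points) < 1) abort("a fiducial set needs at least one point")
  if (anyDuplicated(points$label)) abort("fiducial labels must be unique")
  if (!all(is.finite(as.matrix(points[c("x", "y", "z")])))) {
    abort("fiducial coordinates must be finite numbers")
  }
  structure(points,
            frame = frame, units = units, role = role,
            class = c("fiducial_set", class(points)))
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> role %s, frame %s [%s], %d points\n",
              fid_role(x), fid_frame(x), fid_units(x), nrow(x)))
  NextMethod()
}

#' Fiducial-set tag accessors
#'
#' @param fs A [fiducial_set()].
#' @return The frame, unit, or role tag (a string), or for `fid_matrix()`
#'   an n-by-3 numeric matrix of coordinates in set order.
#' @name fiducial-accessors
#' @export
fid_frame <- function(fs) attr(fs, "frame", exact = TRUE)

#' @rdname fiducial-accessors
#' @export
fid_units <- function(fs) attr(fs, "units", exact = TRUE)

#' @rdname fiducial-accessors
#' @export
fid_role <- function(fs) attr(fs, "role", exact = TRUE)

#' @rdname fiducial-accessors
#' @export
fid_matrix <- function(fs) {
  m <- cbind(x = fs$x, y = fs$y, z = fs$z)
  rownames(m) <- as.character(fs$label)
  m
}

# shared check used by registration and metric code: identical labels in
# identical order, same frame and unit tags
check_matched_sets <- function(a, b, what_a = "first", what_b = "second") {
  if (nrow(a) != nrow(b)) {
    abort(sprintf("point sets differ in size (%d vs %d)", nrow(a), nrow(b)))
  }
  if (!identical(as.character(a$label), as.character(b$label))) {
    abort(sprintf("fiducial labels of the %s and %s set do not match in order",
                  what_a, what_b))
  }
  if (!identical(fid_frame(a), fid_frame(b)) ||
      !identical(fid_units(a), fid_units(b))) {
    abort(sprintf(
      "point sets live in different frames/units: %s [%s] vs %s [%s]",
      fid_frame(a), fid_units(a), fid_frame(b), fid_units(b)))
  }
  invisible(TRUE)
}
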