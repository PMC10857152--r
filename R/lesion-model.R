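#' Binary lesion masks on a regular voxel grid
#'
#' A `lesion_model` is a binary 3-D voxel mask with its grid geometry:
#' voxel `spacing` (mm along each axis), the RAS `origin` of the centre of
#' voxel `(0, 0, 0)` (0-based indices), and a 3x3 `direction` matrix giving
#' the world direction of each index axis. The physical position of voxel
#' `(i, j, k)` (0-based) is `origin + direction %*% (spacing * c(i, j, k))`.
#' The centroid (mean of foreground voxel centres, RAS mm) and the volume
#' (foreground voxel count times the voxel volume, cm^3) are derived on
#' construction.
#'
#' @param mask 3-D array, logical or 0/1 numeric; must contain at least one
#'   foreground voxel.
#' @param spacing Voxel size, length 3, mm.
#' @param origin RAS position (mm) of the centre of voxel (0, 0, 0).
#' @param direction 3x3 orientation matrix (columns of unit norm);
#'   identity for an axis-aligned RAS grid.
#'
#' @return A `lesion_model` with elements `mask`, `spacing`, `origin`,
#'   `direction`, `centroid` (RAS mm) and `volume` (cm^3).
#' @examples
#' m <- array(FALSE, c(20, 20, 20)); m[5:15, 5:15, 5:15] <- TRUE
#' les <- lesion_model(m, spacing = c(1, 1, 1), origin = c(-10, -10, -10))
#' les$volume  # 11^3 voxels = 1.331 cm^3
#' @export
lesion_model <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (length(dim(mask)) != 3) abort("lesion mask must be a 3-D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) abort("lesion mask is empty")
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3,
            identical(dim(direction), c(3L, 3L)))
  idx <- which(mask, arr.ind = TRUE) - 1  # 0-based
  centres <- voxel_to_world(idx, spacing, origin, direction)
  structure(
    list(mask = mask, spacing = as.numeric(spacing),
         origin = as.numeric(origin), direction = direction,
         centroid = colMeans(centres),
         volume = sum(mask) * prod(spacing) / 1000),
    class = "lesion_model")
}

#' @export
print.lesion_model <- function(x, ...) {
  cat(sprintf(
    "<lesion_model> %s grid @ %s mm, %d voxels, volume %.2f cm^3\n",
    paste(dim(x$mask), collapse = "x"),
    paste(signif(x$spacing, 3), collapse = "x"),
    sum(x$mask), x$volume))
  cat("centroid (RAS mm):", round(x$centroid, 2), "\n")
  invisible(x)
}

# n x 3 matrix of 0-based indices -> RAS mm
voxel_to_world <- function(idx0, spacing, origin, direction) {
  xyz <- sweep(idx0, 2, spacing, `*`) %*% t(direction)
  sweep(xyz, 2, origin, `+`)
}

# RAS mm -> continuous 0-based indices
world_to_voxel <- function(xyz, spacing, origin, direction) {
  rel <- sweep(xyz, 2, origin) %*% direction  # direction orthonormal: inv = t
  sweep(rel, 2, spacing, `/`)
}

# RAS mm centres of every voxel on the grid, in array order
grid_centres <- function(les) {
  d <- dim(les$mask)
  idx0 <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(idx0, les$spacing, les$origin, les$direction)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$mask), dim(b$mask)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}
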