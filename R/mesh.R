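#' Triangulated surface meshes
#'
#' A minimal triangle-mesh container: `vertices` is an n-by-3 matrix of RAS
#' mm coordinates, `faces` an m-by-3 integer matrix of 1-based vertex
#' indices. Used for the phantom's skin surface.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of vertex indices.
#' @return A `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3, nrow(faces) >= 1)
  storage.mode(faces) <- "integer"
  if (min(faces) < 1 || max(faces) > nrow(vertices)) {
    abort("face indices out of range")
  }
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Triangulated ellipsoid
#'
#' A UV-sphere triangulation scaled to the given semi-axes: two pole
#' vertices plus `n_lat` latitude rings of `n_lon` vertices, pole fans and
#' quad strips split into triangles. The default semi-axes approximate an
#' adult head (RAS half-widths 80, 95, 85 mm).
#'
#' @param semi_axes Semi-axes along x (right), y (anterior), z (superior),
#'   mm.
#' @param center Centre of the ellipsoid, RAS mm.
#' @param n_lat,n_lon Latitude rings / longitudinal divisions.
#' @return A [surface_mesh()].
#' @export
ellipsoid_mesh <- function(semi_axes = c(80, 95, 85), center = c(0, 0, 0),
                           n_lat = 24, n_lon = 48) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), n_lat >= 2,
            n_lon >= 3)
  theta <- pi * seq_len(n_lat) / (n_lat + 1)
  phi <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  ring <- function(t) {
    cbind(semi_axes[1] * sin(t) * cos(phi),
          semi_axes[2] * sin(t) * sin(phi),
          semi_axes[3] * cos(t))
  }
  verts <- rbind(c(0, 0, semi_axes[3]),
                 do.call(rbind, lapply(theta, ring)),
                 c(0, 0, -semi_axes[3]))
  verts <- sweep(verts, 2, center, `+`)
  north <- 1L
  south <- nrow(verts)
  ridx <- function(i, j) 1L + (i - 1L) * n_lon + j  # ring i, slot j (1-based)
  jn <- c(seq_len(n_lon)[-1], 1L)                   # next slot, wrapping
  faces <- rbind(
    cbind(north, ridx(1L, seq_len(n_lon)), ridx(1L, jn)),
    do.call(rbind, lapply(seq_len(n_lat - 1L), function(i) {
      rbind(cbind(ridx(i, seq_len(n_lon)), ridx(i + 1L, seq_len(n_lon)),
                  ridx(i + 1L, jn)),
            cbind(ridx(i, seq_len(n_lon)), ridx(i + 1L, jn), ridx(i, jn)))
    })),
    cbind(south, ridx(n_lat, jn), ridx(n_lat, seq_len(n_lon))))
  surface_mesh(verts, faces)
}

#' Exact distances from a point to every mesh triangle
#'
#' For each triangle the closest point is either the orthogonal projection
#' onto the triangle's plane (when that projection falls inside the
#' triangle) or a point on one of its edges; the edge case reduces to
#' point-to-segment distances. Degenerate (zero-area) triangles fall back
#' to their edge distances; a mesh consisting only of degenerate triangles
#' is an error.
#'
#' @param p Query point, length 3 (mm).
#' @param mesh A [surface_mesh()].
#' @return Numeric vector of distances (mm), one per triangle.
#' @export
point_triangle_distances <- function(p, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"), length(p) == 3)
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c3 <- v[mesh$faces[, 3], , drop = FALSE]
  e0 <- b - a
  e1 <- c3 - a
  aa <- rowSums(e0 * e0)
  bb <- rowSums(e0 * e1)
  cc <- rowSums(e1 * e1)
  det <- aa * cc - bb^2
  degenerate <- det <= 1e-12 * pmax(aa * cc, 1e-300)
  if (all(degenerate)) abort("mesh has only zero-area triangles")

  w <- -sweep(a, 2, p)  # p - a, rowwise
  d0 <- rowSums(w * e0)
  e0d <- rowSums(w * e1)
  ff <- rowSums(w * w)

  seg_d2 <- function(orig, dir, len2) {
    wo <- -sweep(orig, 2, p)
    t <- rowSums(wo * dir) / pmax(len2, 1e-300)
    t <- pmin(1, pmax(0, t))
    diff <- wo - dir * t
    rowSums(diff * diff)
  }
  edge2 <- pmin(seg_d2(a, e0, aa),
                seg_d2(a, e1, cc),
                seg_d2(b, c3 - b, rowSums((c3 - b)^2)))

  s <- (cc * d0 - bb * e0d) / det
  t <- (aa * e0d - bb * d0) / det
  inside <- !degenerate & s >= 0 & t >= 0 & (s + t) <= 1
  plane2 <- ff - s * d0 - t * e0d

  d2 <- ifelse(inside, pmax(0, plane2), edge2)
  sqrt(d2)
}

#' Read and write triangle meshes (ASCII STL, OBJ)
#'
#' `write_mesh()`/`read_mesh()` support ASCII STL (triangle soup; vertices
#' are deduplicated on read) and Wavefront OBJ (`v`/`f` records; polygonal
#' faces are fan-triangulated). The format is taken from the file
#' extension unless given explicitly. Binary STL is not supported.
#'
#' @param mesh A [surface_mesh()].
#' @param path File path (`.stl` or `.obj`).
#' @param format `"stl"`, `"obj"`, or `"auto"` (from the extension).
#' @return `read_mesh()` returns a [surface_mesh()]; `write_mesh()` the
#'   path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "obj")) {
  format <- resolve_mesh_format(match.arg(format), path)
  stopifnot(inherits(mesh, "surface_mesh"))
  if (format == "obj") {
    lines <- c(
      sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1], mesh$vertices[, 2],
              mesh$vertices[, 3]),
      sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
              mesh$faces[, 3]))
  } else {
    tri <- function(k) mesh$vertices[mesh$faces[, k], , drop = FALSE]
    v1 <- tri(1); v2 <- tri(2); v3 <- tri(3)
    n <- vector_cross(v2 - v1, v3 - v1)
    nn <- sqrt(rowSums(n^2))
    n <- n / ifelse(nn > 0, nn, 1)
    lines <- c("solid mesh",
               as.vector(rbind(
                 sprintf("  facet normal %.9g %.9g %.9g",
                         n[, 1], n[, 2], n[, 3]),
                 "    outer loop",
                 sprintf("      vertex %.17g %.17g %.17g",
                         v1[, 1], v1[, 2], v1[, 3]),
                 sprintf("      vertex %.17g %.17g %.17g",
                         v2[, 1], v2[, 2], v2[, 3]),
                 sprintf("      vertex %.17g %.17g %.17g",
                         v3[, 1], v3[, 2], v3[, 3]),
                 "    endloop",
                 "  endfacet")),
               "endsolid mesh")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = c("auto", "stl", "obj")) {
  format <- resolve_mesh_format(match.arg(format), path)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (any(readBin(path, "raw", n = 512) == as.raw(0))) {
    abort("binary mesh files are not supported; export as ASCII")
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "obj") {
    vlines <- grep("^v\\s", lines, value = TRUE)
    flines <- grep("^f\\s", lines, value = TRUE)
    if (length(vlines) == 0 || length(flines) == 0) {
      abort("OBJ file has no vertices or no faces")
    }
    verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                   function(f) as.numeric(f[2:4])))
    faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"),
                                   function(f) {
      idx <- as.integer(sub("/.*$", "", f[-1]))
      if (length(idx) < 3) abort("OBJ face with fewer than 3 vertices")
      cbind(idx[1], idx[-c(1, length(idx))], idx[-(1:2)])  # fan
    }))
    return(surface_mesh(verts, faces))
  }
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
    abort("malformed ASCII STL: vertex count is not a multiple of 3")
  }
  soup <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                function(f) as.numeric(f[2:4])))
  key <- apply(round(soup, 9), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- soup[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

resolve_mesh_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("stl", "obj")) return(ext)
  abort(paste0("cannot infer mesh format from extension: ", path))
}

vector_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}
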