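#' Triangulated surface mesh
#'
#' Construct a `surface_mesh`: the geometric substrate for all per-vertex
#' fields in the package. Coordinates are in millimetres throughout; no
#' implicit rescaling is ever applied.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer M x 3 matrix of 1-based vertex indices with
#'   consistent (counter-clockwise seen from outside) winding.
#' @param normals optional N x 3 matrix of outward unit vertex normals.
#'   When `NULL`, area-weighted normals are computed from the faces.
#' @param point_data optional named list of per-vertex numeric vectors
#'   (length N each) carried with the mesh, VTK-style.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `normals`, `point_data`.
#' @examples
#' m <- make_aneurysm_mesh(synthetic_spec(n_theta = 16, n_z = 24))
#' nrow(m$vertices)
#' @export
surface_mesh <- function(vertices, faces, normals = NULL, point_data = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix")
  n <- nrow(vertices)
  if (n < 3L || nrow(faces) < 1L) stop("mesh must have >= 3 vertices and >= 1 face")
  if (min(faces) < 1L || max(faces) > n) {
    stop("face indices out of range [1, ", n, "]")
  }
  areas <- face_areas(vertices, faces)
  if (any(areas <= .Machine$double.eps)) {
    stop("mesh contains degenerate (zero-area) faces")
  }
  if (is.null(normals)) {
    normals <- vertex_normals(vertices, faces)
  } else {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    dimnames(normals) <- NULL
    if (!all(dim(normals) == dim(vertices))) stop("normals must match vertices in shape")
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-6)) stop("vertex normals must be unit length (tol 1e-6)")
  }
  stopifnot(is.list(point_data))
  if (length(point_data)) {
    ok <- vapply(point_data, function(x) length(x) == n, logical(1))
    if (!all(ok)) stop("point_data arrays must have one value per vertex")
  }
  structure(
    list(vertices = vertices, faces = faces, normals = normals,
         point_data = point_data),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (length(x$point_data)) {
    cat(sprintf(", point data: %s", paste(names(x$point_data), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

# Unnormalized face normals; their norm is twice the face area, so summing
# them per incident vertex gives area weighting for free.
face_cross <- function(vertices, faces) {
  v1 <- vertices[faces[, 1L], , drop = FALSE]
  e1 <- vertices[faces[, 2L], , drop = FALSE] - v1
  e2 <- vertices[faces[, 3L], , drop = FALSE] - v1
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

#' Triangle areas of a surface mesh
#'
#' @param vertices N x 3 coordinate matrix (mm).
#' @param faces M x 3 index matrix.
#' @return numeric vector of M face areas (mm^2).
#' @export
face_areas <- function(vertices, faces) {
  cr <- face_cross(vertices, faces)
  0.5 * sqrt(rowSums(cr^2))
}

#' Area-weighted outward vertex normals
#'
#' Each vertex normal is the normalized sum of the (area-weighted) normals of
#' its incident faces; orientation follows the face winding.
#'
#' @inheritParams face_areas
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(vertices, faces) {
  cr <- face_cross(vertices, faces)
  n <- nrow(vertices)
  acc <- matrix(0, n, 3L)
  for (j in 1:3) {
    for (k in 1:3) {
      s <- rowsum(cr[, k], group = faces[, j], reorder = FALSE)
      idx <- as.integer(rownames(s))
      acc[idx, k] <- acc[idx, k] + s[, 1L]
    }
  }
  len <- sqrt(rowSums(acc^2))
  if (any(len <= .Machine$double.eps)) {
    stop("degenerate vertex normal (vertex with cancelling or no incident faces)")
  }
  acc / len
}

#' Signed volume enclosed by a closed mesh
#'
#' Divergence-theorem volume; positive when face winding is outward. Used to
#' check orientation consistency of closed meshes.
#'
#' @param mesh a [surface_mesh()].
#' @return signed volume (mm^3).
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
      a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
      a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])) / 6
}

#' Per-vertex area share
#'
#' One third of the total area of the faces incident to each vertex; the
#' barycentric lumping used when converting vertex masks to surface areas.
#'
#' @param mesh a [surface_mesh()].
#' @return numeric vector of N vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  areas <- face_areas(mesh$vertices, mesh$faces)
  n <- nrow(mesh$vertices)
  acc <- numeric(n)
  for (j in 1:3) {
    s <- rowsum(areas, group = mesh$faces[, j], reorder = FALSE)
    idx <- as.integer(rownames(s))
    acc[idx] <- acc[idx] + s[, 1L]
  }
  acc / 3
}

#' Restrict a mesh to a vertex subset
#'
#' Keeps the selected vertices and the faces whose three corners all survive;
#' point-data arrays are subset alongside.
#'
#' @param mesh a [surface_mesh()].
#' @param keep logical vector (length N) or integer vertex indices.
#' @return a new `surface_mesh`. Normals are carried over, not recomputed, so
#'   per-vertex quantities computed on the submesh match the parent mesh.
#' @export
submesh <- function(mesh, keep) {
  n <- nrow(mesh$vertices)
  if (is.logical(keep)) {
    stopifnot(length(keep) == n)
    keep <- which(keep)
  }
  keep <- as.integer(keep)
  map <- integer(n)
  map[keep] <- seq_along(keep)
  fkeep <- rowSums(matrix(mesh$faces %in% keep, ncol = 3L)) == 3L
  if (!any(fkeep)) stop("submesh has no surviving faces")
  faces <- matrix(map[mesh$faces[fkeep, , drop = FALSE]], ncol = 3L)
  surface_mesh(mesh$vertices[keep, , drop = FALSE], faces,
               normals = mesh$normals[keep, , drop = FALSE],
               point_data = lapply(mesh$point_data, function(x) x[keep]))
}
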