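#' Triangle mesh
#'
#' A closed, consistently oriented triangle surface with vertices in world
#' millimetres.  Meshes carry a structure's volume across time points: the
#' baseline mesh is extracted from a segmentation, the follow-up mesh is the
#' same mesh pushed through a transform or displacement field, so no
#' resampling error enters the volume change.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices; consistent
#'   outward orientation gives a positive signed volume.
#' @param check if `TRUE` (default) verify index ranges and closedness.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, check = TRUE) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  storage.mode(vertices) <- "double"
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("'vertices' must be n x 3")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (check) {
    if (nrow(faces) == 0L) stop("mesh has no faces")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, volume %.3f mm^3\n",
              nrow(x$vertices), nrow(x$faces),
              tryCatch(mesh_volume(x, warn_negative = FALSE),
                       error = function(e) NA_real_)))
  invisible(x)
}

#' Is a mesh a closed 2-manifold surface?
#'
#' Checks that every undirected edge is shared by exactly two faces and that
#' the two incident faces traverse it in opposite directions (consistent
#' orientation).
#'
#' @param mesh a [triangle_mesh()].
#' @return Logical scalar.
#' @export
mesh_is_closed <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to   <- c(f[, 2], f[, 3], f[, 1])
  nv <- nrow(mesh$vertices)
  dir_key <- (from - 1) * nv + (to - 1)        # directed half-edges
  und_key <- pmin(from, to) * (nv + 1.0) + pmax(from, to)
  und_tab <- table(und_key)
  if (any(und_tab != 2L)) return(FALSE)
  # consistent orientation: each directed half-edge appears exactly once
  !anyDuplicated(dir_key)
}

#' Mesh volume by signed tetrahedra
#'
#' The enclosed volume of a closed triangle mesh, computed as the sum over
#' faces of the signed volume of the tetrahedron formed by the origin and the
#' triangle's three vertices.  For a closed surface this sum is independent of
#' the origin (divergence theorem), hence translation-invariant, and positive
#' when faces are oriented outward.
#'
#' @param mesh a [triangle_mesh()].
#' @param signed if `TRUE` return the raw signed sum; otherwise (default) the
#'   magnitude is returned and a warning is logged when the signed sum is
#'   negative (inward orientation).
#' @param warn_negative emit the orientation warning (default `TRUE`).
#' @param check_closed verify closedness first (default `TRUE`); a non-closed
#'   mesh is an error ("open surface") because the tetrahedron sum is then
#'   origin-dependent and meaningless.
#' @return Volume in mm^3.
#' @examples
#' cube <- unit_cube_mesh()
#' mesh_volume(cube)  # 1
#' @export
mesh_volume <- function(mesh, signed = FALSE, warn_negative = TRUE,
                        check_closed = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (check_closed && !mesh_is_closed(mesh))
    stop("open surface: mesh is not a closed oriented 2-manifold")
  v <- .mesh_signed_volume(mesh$vertices, mesh$faces)
  if (signed) return(v)
  if (v < 0 && warn_negative)
    warning("negative signed volume: mesh appears inward-oriented; returning magnitude")
  abs(v)
}

#' Homogeneous affine transform
#'
#' @param matrix 4x4 homogeneous matrix (mm to mm), last row (0,0,0,1).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix) {
  structure(list(matrix = validate_affine(matrix)), class = "affine_transform")
}

#' Apply an affine transform to a mesh
#'
#' Vertices are mapped exactly, with no resampling; connectivity is
#' unchanged.  The mesh volume scales by `abs(det)` of the 3x3 block.
#'
#' @param mesh a [triangle_mesh()].
#' @param transform an [affine_transform()] or plain 4x4 matrix.
#' @return The transformed [triangle_mesh()].
#' @export
apply_affine <- function(mesh, transform) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  m <- if (inherits(transform, "affine_transform")) transform$matrix
       else validate_affine(transform)
  v <- t(m %*% rbind(t(mesh$vertices), 1))[, 1:3, drop = FALSE]
  triangle_mesh(v, mesh$faces, check = FALSE)
}

#' Centroid of a mesh's vertices
#' @param mesh a [triangle_mesh()].
#' @return Length-3 numeric vector (mm).
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Axis-aligned unit cube test mesh
#'
#' A 12-triangle, outward-oriented unit cube with one corner at `origin`;
#' used in examples and as a volumetry oracle.
#'
#' @param origin corner position, default `c(0,0,0)`.
#' @return A [triangle_mesh()] with volume 1.
#' @export
unit_cube_mesh <- function(origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  v <- sweep(v, 2, origin, "+")
  # outward-oriented quads split into triangles (vertex rows follow
  # expand.grid order: index = 1 + x + 2y + 4z)
  quads <- rbind(
    c(1, 3, 4, 2),  # z = 0, normal -z
    c(5, 6, 8, 7),  # z = 1, normal +z
    c(1, 2, 6, 5),  # y = 0, normal -y
    c(3, 7, 8, 4),  # y = 1, normal +y
    c(1, 5, 7, 3),  # x = 0, normal -x
    c(2, 4, 8, 6))  # x = 1, normal +x
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(q) {
    rbind(quads[q, c(1, 2, 3)], quads[q, c(1, 3, 4)])
  }))
  triangle_mesh(v, f)
}
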