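#' Extract an isosurface mesh from a binary segmentation
#'
#' Runs marching cubes on the 0/1 voxel grid at `iso_level` (default 0.5, the
#' unbiased midpoint for binary masks; no pre-smoothing is applied) and maps
#' the resulting vertices to world millimetres through the volume's affine.
#' The implementation traces marching-squares segments on each cell face and
#' resolves ambiguous (diagonal) faces with the foreground-connected rule, so
#' the returned surface is always a closed, consistently oriented 2-manifold.
#'
#' If foreground touches the grid boundary the grid is padded with one layer
#' of background first (logged), so the surface can never be clipped open.
#'
#' @param seg a [label_volume()] with at least one foreground voxel.
#' @param iso_level iso value strictly inside (0, 1); default 0.5.
#' @return A [triangle_mesh()] in world mm with outward orientation.
#' @examples
#' seg <- make_segmentation(shape_spec(semi_axes = c(6, 5, 4)))
#' m <- extract_mesh(seg)
#' mesh_volume(m)
#' @export
extract_mesh <- function(seg, iso_level = 0.5) {
  stopifnot(inherits(seg, "label_volume"))
  if (!is.numeric(iso_level) || iso_level <= 0 || iso_level >= 1)
    stop("'iso_level' must lie strictly between 0 and 1")
  if (sum(seg$data) == 0L) stop("empty label: no foreground voxels")

  arr <- seg$data
  affine <- seg$affine
  if (touches_boundary(arr)) {
    arr <- pad_array(arr)
    # voxel (1,1,1) of the padded grid is voxel (0,0,0) of the original
    shift <- affine[1:3, 1:3] %*% c(-1, -1, -1)
    affine[1:3, 4] <- affine[1:3, 4] + shift
    log_event("foreground touches grid boundary; padded one background layer")
  }

  raw <- .mc_extract(as.numeric(arr), dim(arr), iso_level)
  verts <- voxel_to_world(raw$vertices, affine)
  mesh <- triangle_mesh(verts, raw$faces, check = FALSE)
  # world affines with negative determinant flip orientation; keep outward
  if (.mesh_signed_volume(mesh$vertices, mesh$faces) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

touches_boundary <- function(arr) {
  d <- dim(arr)
  sum(arr[c(1, d[1]), , ]) + sum(arr[, c(1, d[2]), ]) + sum(arr[, , c(1, d[3])]) > 0
}

pad_array <- function(arr) {
  d <- dim(arr)
  out <- array(0L, d + 2L)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  out
}
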