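#' Jacobian determinant map of a displacement field
#'
#' Computes the per-voxel determinant of the deformation gradient
#' `J = I + du/dx` of the mapping `x -> x + u(x)`, with spatial derivatives
#' taken in world millimetres: central differences in the grid interior and
#' one-sided second-order stencils at grid edges.  The determinant is the
#' local volume-scaling factor of the deformation; it equals 1 everywhere for
#' the zero field and is strictly positive for diffeomorphic-style inputs
#' (violations are counted, logged and reported, not silently dropped).
#'
#' Grids whose affine is axis-aligned or rotated are supported (index-space
#' derivatives are mapped through the affine's 3x3 block); sheared affines
#' are rejected because the determinant would then mix non-orthogonal
#' directions the bookkeeping does not model.
#'
#' @param field a [displacement_field()] with at least 3 voxels per axis.
#' @return A `jacobian_map` object: list with `det` (3-D array), `affine`,
#'   `spacing`, and `n_nonpositive` (count of non-positive determinants).
#' @export
jacobian_map <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  d <- dim(field$vectors)[1:3]
  if (any(d < 3L)) stop("grid must have at least 3 voxels per axis")
  A3 <- field$affine[1:3, 1:3]
  # reject shear: columns of the voxel->world block must be orthogonal
  cross <- crossprod(A3)
  offdiag <- cross[upper.tri(cross)]
  if (any(abs(offdiag) > 1e-6 * max(diag(cross))))
    stop("oblique grid unsupported: sheared voxel-to-world affine")
  A3inv <- solve(A3)

  # index-space partial derivatives of each displacement component
  du <- array(0, c(d, 3, 3))  # du[,,c, comp, axis]
  for (comp in 1:3) {
    uc <- field$vectors[, , , comp]
    du[, , , comp, 1] <- diff_axis(uc, 1)
    du[, , , comp, 2] <- diff_axis(uc, 2)
    du[, , , comp, 3] <- diff_axis(uc, 3)
  }
  n <- prod(d)
  G <- matrix(du, n, 9)  # columns: (comp, axis) pairs, comp fastest
  # world-space gradient: Dw[comp, j] = sum_axis G[comp, axis] * A3inv[axis, j]
  detj <- numeric(n)
  Dw <- array(0, c(n, 3, 3))
  for (comp in 1:3)
    for (jj in 1:3)
      Dw[, comp, jj] <- G[, comp + 3 * (1:3 - 1)] %*% A3inv[, jj]
  a11 <- 1 + Dw[, 1, 1]; a12 <- Dw[, 1, 2]; a13 <- Dw[, 1, 3]
  a21 <- Dw[, 2, 1]; a22 <- 1 + Dw[, 2, 2]; a23 <- Dw[, 2, 3]
  a31 <- Dw[, 3, 1]; a32 <- Dw[, 3, 2]; a33 <- 1 + Dw[, 3, 3]
  detj <- a11 * (a22 * a33 - a23 * a32) -
          a12 * (a21 * a33 - a23 * a31) +
          a13 * (a21 * a32 - a22 * a31)
  detj <- array(detj, d)
  npos <- sum(detj <= 0)
  if (npos > 0)
    log_event("%d voxels with non-positive Jacobian determinant", npos)
  structure(list(det = detj, affine = field$affine, spacing = field$spacing,
                 n_nonpositive = npos),
            class = "jacobian_map")
}

# Central differences along one array axis (index units), second-order
# one-sided at the two boundary slices.
diff_axis <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  out <- matrix(0, n, ncol(m))
  out[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) / 2
  out[1, ] <- (-3 * m[1, ] + 4 * m[2, ] - m[3, ]) / 2
  out[n, ] <- ( 3 * m[n, ] - 4 * m[n - 1, ] + m[n - 2, ]) / 2
  aperm(array(out, d[perm]), order(perm))
}

#' @export
print.jacobian_map <- function(x, ...) {
  cat(sprintf("jacobian_map: %s grid, det in [%.4f, %.4f], %d non-positive\n",
              paste(dim(x$det), collapse = "x"), min(x$det), max(x$det),
              x$n_nonpositive))
  invisible(x)
}

#' Integrate Jacobian determinants over a segmentation
#'
#' The follow-up volume of a region by the deformation-based route: the sum
#' of the Jacobian determinant over the region's foreground voxels times the
#' voxel volume.  With the zero field this is exactly the voxel-count volume
#' of the segmentation.
#'
#' @param jac a [jacobian_map()].
#' @param seg a [label_volume()] on the same grid.
#' @return Follow-up volume in mm^3.
#' @export
integrate_jacobian <- function(jac, seg) {
  stopifnot(inherits(jac, "jacobian_map"), inherits(seg, "label_volume"))
  if (!identical(dim(jac$det), dim(seg$data)) ||
      max(abs(jac$affine - seg$affine)) > 1e-6)
    stop("grid mismatch between Jacobian map and segmentation")
  sum(jac$det[seg$data == 1L]) * voxel_volume(seg)
}

#' Write a Jacobian map as a scalar NIfTI image
#' @param jac a [jacobian_map()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_jacobian_map <- function(jac, path) {
  stopifnot(inherits(jac, "jacobian_map"))
  img <- RNifti::asNifti(jac$det)
  img <- RNifti::`sform<-`(img, structure(jac$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(jac$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
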