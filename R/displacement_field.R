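#' Dense displacement field
#'
#' A per-voxel field of 3-D world-space displacement vectors (mm) on a grid
#' with its own voxel-to-world affine.  It represents the non-linear mapping
#' `x -> x + u(x)` produced by a registration between the baseline and
#' follow-up scans; the `direction` tag records which way the field pushes
#' points and is mandatory, because warping a baseline mesh requires a
#' baseline-to-follow-up field.
#'
#' @param vectors numeric 4-D array `nx x ny x nz x 3` of displacements (mm).
#' @param spacing voxel spacing (mm), ignored when `affine` is given.
#' @param affine 4x4 voxel-to-world transform of the vector grid.
#' @param direction `"baseline_to_followup"` or `"followup_to_baseline"`.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1), affine = NULL,
                               direction = c("baseline_to_followup",
                                             "followup_to_baseline")) {
  direction <- match.arg(direction)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("'vectors' must be an nx x ny x nz x 3 array")
  if (any(!is.finite(vectors))) stop("displacement field contains non-finite values")
  if (is.null(affine)) {
    if (any(spacing <= 0)) stop("'spacing' must be positive")
    affine <- diag(c(spacing, 1))
  } else {
    affine <- validate_affine(affine)
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 affine = affine, direction = direction),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field: %s grid, %s, max |u| = %.3f mm\n",
              paste(dim(x$vectors)[1:3], collapse = "x"), x$direction,
              sqrt(max(rowSums(matrix(x$vectors, ncol = 3)^2)))))
  invisible(x)
}

#' Sample a displacement field at world-space points
#'
#' Component-wise trilinear interpolation of the vector grid at each point's
#' voxel-space position.  Points outside the grid bounding box receive zero
#' displacement; their count is logged and returned as an attribute.
#'
#' @param field a [displacement_field()].
#' @param points numeric n x 3 matrix of world-mm positions.
#' @return n x 3 matrix of displacements (mm) with attribute
#'   `n_outside`, the number of out-of-domain points.
#' @export
sample_displacement <- function(field, points) {
  stopifnot(inherits(field, "displacement_field"))
  points <- rbind(points)
  if (any(!is.finite(points))) stop("non-finite sample point")
  vox <- world_to_voxel(points, field$affine)
  d <- dim(field$vectors)[1:3]
  eps <- 1e-9
  inside <- vox[, 1] >= -eps & vox[, 1] <= d[1] - 1 + eps &
            vox[, 2] >= -eps & vox[, 2] <= d[2] - 1 + eps &
            vox[, 3] >= -eps & vox[, 3] <= d[3] - 1 + eps
  n_out <- sum(!inside)
  if (n_out > 0)
    log_event("%d of %d sample points outside field domain; zero displacement used",
              n_out, nrow(points))
  out <- matrix(0, nrow(points), 3)
  if (any(inside)) {
    p <- pmin(pmax(vox[inside, , drop = FALSE], 0),
              matrix(d - 1, sum(inside), 3, byrow = TRUE))
    i0 <- pmin(floor(p[, 1]), d[1] - 2); j0 <- pmin(floor(p[, 2]), d[2] - 2)
    k0 <- pmin(floor(p[, 3]), d[3] - 2)
    fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
    for (comp in 1:3) {
      arr <- field$vectors[, , , comp]
      idx <- function(di, dj, dk)
        arr[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
      val <- idx(0,0,0) * (1-fx)*(1-fy)*(1-fz) + idx(1,0,0) * fx*(1-fy)*(1-fz) +
             idx(0,1,0) * (1-fx)*fy*(1-fz)     + idx(1,1,0) * fx*fy*(1-fz) +
             idx(0,0,1) * (1-fx)*(1-fy)*fz     + idx(1,0,1) * fx*(1-fy)*fz +
             idx(0,1,1) * (1-fx)*fy*fz         + idx(1,1,1) * fx*fy*fz
      out[inside, comp] <- val
    }
  }
  attr(out, "n_outside") <- n_out
  out
}

#' Warp a mesh through a displacement field
#'
#' Moves every vertex to `x + u(x)` (trilinear sampling of the field, no
#' resampling of the mesh); connectivity is unchanged.  The result is the
#' follow-up-space mesh whose volume is the follow-up volume `V_FU`.
#'
#' @param mesh a [triangle_mesh()] in the field's world space.
#' @param field a [displacement_field()] with direction
#'   `baseline_to_followup`.
#' @param max_outside_frac error if more than this fraction of vertices fall
#'   outside the field domain (default 0.01).
#' @return The warped [triangle_mesh()].
#' @export
warp_mesh <- function(mesh, field, max_outside_frac = 0.01) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(field, "displacement_field"))
  if (field$direction != "baseline_to_followup")
    stop("field direction must be 'baseline_to_followup' to warp a baseline mesh")
  u <- sample_displacement(field, mesh$vertices)
  if (attr(u, "n_outside") > max_outside_frac * nrow(mesh$vertices))
    stop("mesh escapes field: more than ",
         sprintf("%.1f%%", 100 * max_outside_frac),
         " of vertices outside the field domain")
  attr(u, "n_outside") <- NULL
  triangle_mesh(mesh$vertices + u, mesh$faces, check = FALSE)
}

#' Read and write NIfTI-1 displacement fields
#'
#' The primary on-disk dialect is a 5-D NIfTI of shape `X x Y x Z x 1 x 3`
#' with vector intent (the convention popularised by the ANTs ecosystem).  A
#' fallback reader accepts plain 4-D `X x Y x Z x 3` images.  Displacements
#' are stored in world mm.
#'
#' @param path NIfTI file path.
#' @param direction direction tag to attach on read (files do not carry one).
#' @return `read_displacement_field()` returns a [displacement_field()];
#'   `write_displacement_field()` returns `path` invisibly.
#' @export
read_displacement_field <- function(path,
                                    direction = "baseline_to_followup") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 5L && d[4] == 1L && d[5] == 3L) {
    dim(arr) <- d[c(1:3, 5)]
  } else if (length(d) == 4L && d[4] == 3L) {
    log_event("reading 4-D (X,Y,Z,3) displacement field dialect")
  } else {
    stop("expected a (X,Y,Z,1,3) or (X,Y,Z,3) vector NIfTI image")
  }
  affine <- unclass(RNifti::xform(img))
  displacement_field(arr, affine = affine, direction = direction)
}

#' @rdname read_displacement_field
#' @param field a [displacement_field()] to write.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  arr <- field$vectors
  dim(arr) <- c(dim(arr)[1:3], 1L, 3L)
  img <- RNifti::asNifti(arr)
  img$intent_code <- 1007L   # NIFTI_INTENT_VECTOR
  img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(field$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
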