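#' Binary label volume
#'
#' A `label_volume` is a 3-D voxel grid of 0/1 labels together with its voxel
#' spacing and a 4x4 voxel-to-world affine (world coordinates in mm, voxel
#' indices 0-based).  It is the container for baseline and follow-up
#' segmentations of the structure whose volume change is being measured.
#'
#' @param data 3-D array; any non-zero value is treated as foreground.
#' @param spacing numeric length-3 voxel spacing in mm (ignored if `affine`
#'   is supplied; derived from it instead).
#' @param affine 4x4 voxel-to-world transform.  Default: axis-aligned scaling
#'   by `spacing` with the origin at voxel (0,0,0).
#' @return An object of class `label_volume` with elements `data` (0/1 integer
#'   array), `spacing`, and `affine`.
#' @examples
#' seg <- label_volume(array(c(0, 1, 1, 0), c(2, 2, 1)), spacing = c(1, 1, 2))
#' voxel_volume(seg)
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D array")
  if (is.null(affine)) {
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("'spacing' must be three positive numbers")
    affine <- diag(c(spacing, 1))
  } else {
    affine <- validate_affine(affine)
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  bin <- array(0L, dim(data))
  bin[data != 0] <- 1L
  structure(list(data = bin, spacing = as.numeric(spacing), affine = affine),
            class = "label_volume")
}

validate_affine <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4, 4)) || any(!is.finite(m)))
    stop("affine must be a finite 4x4 matrix")
  if (any(abs(m[4, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("last row of affine must be (0, 0, 0, 1)")
  if (abs(det(m[1:3, 1:3])) < 1e-12) stop("affine is singular")
  m
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %s grid, %d foreground voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Volume of one voxel in mm^3
#'
#' @param vol a [label_volume()].
#' @return Scalar voxel volume, `abs(det)` of the affine's 3x3 block.
#' @export
voxel_volume <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  abs(det(vol$affine[1:3, 1:3]))
}

#' Voxel-count volume of a segmentation
#'
#' The zeroth-order volume estimate: number of foreground voxels times the
#' voxel volume.  Used as the baseline volume of the Jacobian-integration
#' route and as a sanity bound for mesh volumes.
#'
#' @param vol a [label_volume()].
#' @return Volume in mm^3.
#' @export
voxel_count_volume <- function(vol) {
  sum(vol$data) * voxel_volume(vol)
}

# Map 0-based voxel index coordinates (n x 3) to world mm through the affine.
voxel_to_world <- function(idx, affine) {
  idx <- rbind(t(idx), 1)
  t(affine %*% idx)[, 1:3, drop = FALSE]
}

world_to_voxel <- function(pts, affine) {
  voxel_to_world(pts, solve(affine))
}

#' Jaccard overlap index of two segmentations
#'
#' Intersection-over-union `|A n B| / |A u B|` of two label volumes on the
#' same grid; 1 for identical masks, 0 for disjoint ones.
#'
#' @param a,b [label_volume()] objects on identical grids.
#' @return Overlap fraction in `[0, 1]`.
#' @examples
#' g <- array(0, c(3, 3, 1))
#' a <- g; a[1:2, 1, 1] <- 1
#' b <- g; b[2:3, 1, 1] <- 1
#' jaccard_index(label_volume(a), label_volume(b))  # 1/3
#' @export
jaccard_index <- function(a, b) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("segmentations must live on identical grids")
  inter <- sum(a$data & b$data)
  uni <- sum(a$data | b$data)
  if (uni == 0) stop("undefined overlap: both masks empty")
  inter / uni
}

#' Read a binary segmentation from NIfTI-1
#'
#' Any integer/float NIfTI image is accepted; non-zero voxels become
#' foreground (logged when the input was not already 0/1).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) {
    if (prod(dim(arr)[-(1:3)]) != 1L)
      stop("expected a scalar 3-D NIfTI image")
    dim(arr) <- dim(arr)[1:3]
  }
  nz <- sum(arr != 0 & arr != 1)
  if (nz > 0) log_event("binarised %d non-{0,1} voxels on load", nz)
  affine <- structure(RNifti::xform(img), class = NULL)
  label_volume(arr, affine = unclass(affine))
}

#' Write a binary segmentation to NIfTI-1
#'
#' @param vol a [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(array(as.integer(vol$data), dim(vol$data)))
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
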