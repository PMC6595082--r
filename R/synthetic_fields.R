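#' Specification of a synthetic deformation field
#'
#' Describes a displacement field with known (analytic or refinable) ground
#' truth regional volume change, emulating the dense fields exported by
#' non-linear registration tools:
#'
#' * `zero` -- identity mapping, ground-truth PVC 0.
#' * `translation` -- rigid shift by `shift` mm, ground-truth PVC 0.
#' * `uniform_scale` -- `u(x) = (S - I)(x - center)` with diagonal scale
#'   factors `scale`; ground-truth PVC `(sx*sy*sz - 1) * 100` exactly.
#' * `radial_gaussian_contraction` -- `u(x) = -k (x - center) exp(-r^2 / (2
#'   sigma^2))`: a smooth, localised contraction of amplitude `k` and width
#'   `sigma` mm, invertible for `k < 1 / (2 exp(-3/2)) ~ 2.24` along the
#'   worst radial direction; ground truth by fine-grid Jacobian integration.
#' * `smooth_random` -- Gaussian-smoothed white-noise vectors (smoothness
#'   `sigma` mm, RMS amplitude `amplitude` mm), emulating the incidental
#'   spatial structure of a real registration output; ground truth by
#'   fine-grid Jacobian integration.
#'
#' @param kind one of the five kinds above.
#' @param scale length-3 scale factors (uniform_scale).
#' @param shift length-3 translation in mm (translation).
#' @param center contraction/scaling centre in world mm; `NULL` = shape/grid
#'   centre at evaluation time.
#' @param k contraction amplitude (radial_gaussian_contraction), in (0, 1).
#' @param sigma width of the contraction / smoothing kernel, mm.
#' @param amplitude RMS displacement of the smooth random field, mm.
#' @param seed RNG seed (smooth_random only).
#' @return A `field_spec` list.
#' @export
field_spec <- function(kind = c("zero", "translation", "uniform_scale",
                                "radial_gaussian_contraction", "smooth_random"),
                       scale = c(0.983, 0.983, 0.983), shift = c(0, 0, 0),
                       center = NULL, k = 0.02, sigma = 10,
                       amplitude = 0.2, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "uniform_scale" && (any(scale <= 0)))
    stop("scale factors must be positive")
  if (kind == "radial_gaussian_contraction") {
    if (k <= 0 || k >= 1)
      stop("parameters outside invertibility bounds: need 0 < k < 1")
    if (sigma <= 0) stop("'sigma' must be positive")
  }
  if (kind == "smooth_random" && (amplitude < 0 || sigma <= 0))
    stop("'amplitude' must be >= 0 and 'sigma' > 0")
  structure(list(kind = kind, scale = as.numeric(scale),
                 shift = as.numeric(shift), center = center, k = k,
                 sigma = sigma, amplitude = amplitude,
                 seed = as.integer(seed)),
            class = "field_spec")
}

#' Realise a synthetic displacement field on a volume's grid
#'
#' Evaluates the field spec at every voxel of `grid`'s lattice and attaches
#' the ground-truth PVC for the digitized shape in `grid` (analytic where a
#' closed form exists, otherwise by Jacobian integration at quarter
#' spacing).
#'
#' @param spec a [field_spec()].
#' @param grid a [label_volume()] providing the lattice (and, for ground
#'   truth, the region).
#' @param ground_truth compute the ground-truth PVC attribute (default
#'   `TRUE`; the fine-grid oracle costs a few seconds on large grids).
#' @return A [displacement_field()] with attributes `pvc_true` and
#'   `field_spec`.
#' @export
make_field <- function(spec, grid, ground_truth = TRUE) {
  stopifnot(inherits(spec, "field_spec"), inherits(grid, "label_volume"))
  d <- dim(grid$data)
  ctr <- field_center(spec, grid)
  u <- with_seed(spec$seed, field_vectors(spec, d, grid$affine, ctr))
  fld <- displacement_field(u, affine = grid$affine,
                            direction = "baseline_to_followup")
  attr(fld, "field_spec") <- spec
  if (ground_truth) attr(fld, "pvc_true") <- field_true_pvc(spec, grid, ctr)
  fld
}

field_center <- function(spec, grid) {
  if (!is.null(spec$center)) return(spec$center)
  d <- dim(grid$data)
  as.vector(grid$affine[1:3, 1:3] %*% ((d - 1) / 2) + grid$affine[1:3, 4])
}

field_vectors <- function(spec, d, affine, ctr) {
  pts <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  w <- voxel_to_world(pts, affine)
  u <- switch(spec$kind,
    zero = matrix(0, nrow(w), 3),
    translation = matrix(spec$shift, nrow(w), 3, byrow = TRUE),
    uniform_scale = sweep(w, 2, ctr) %*% diag(spec$scale - 1),
    radial_gaussian_contraction = {
      x <- sweep(w, 2, ctr)
      r2 <- rowSums(x^2)
      -spec$k * x * exp(-r2 / (2 * spec$sigma^2))
    },
    smooth_random = smooth_random_vectors(spec, d, affine))
  array(u, c(d, 3))
}

# White noise per voxel and component, smoothed with a separable Gaussian
# kernel of sd sigma (mm), then scaled to the requested RMS amplitude.
smooth_random_vectors <- function(spec, d, affine) {
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  u <- array(rnorm(prod(d) * 3), c(d, 3))
  for (comp in 1:3)
    for (axis in 1:3)
      u[, , , comp] <- gauss_smooth_axis(u[, , , comp], axis,
                                         spec$sigma / sp[axis])
  rms <- sqrt(mean(u^2))
  u * (spec$amplitude / rms)
}

gauss_smooth_axis <- function(arr, axis, sigma_vox) {
  n <- dim(arr)[axis]
  half <- min(max(1L, ceiling(3 * sigma_vox)), n - 1L)  # kernel capped at grid size
  kern <- exp(-(seq(-half, half))^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  # reflect-pad convolution along columns
  padded <- rbind(m[rev(seq_len(half)), , drop = FALSE], m,
                  m[n - seq_len(half) + 1, , drop = FALSE])
  sm <- apply(padded, 2, function(col)
    stats::filter(col, kern, sides = 2)[half + seq_len(n)])
  aperm(array(sm, dim(arr)[perm]), order(perm))
}

# Ground-truth regional PVC: exact for affine-type fields; fine-grid
# Jacobian integration (quarter spacing) for the smooth kinds.
field_true_pvc <- function(spec, grid, ctr) {
  if (spec$kind %in% c("zero", "translation")) return(0)
  if (spec$kind == "uniform_scale") return((prod(spec$scale) - 1) * 100)
  shape <- attr(grid, "shape_spec")
  if (is.null(shape))
    stop("ground truth for smooth fields needs a grid from make_segmentation()")
  fine_spec <- shape
  fine_spec$spacing <- shape$spacing / 4
  fine_seg <- make_segmentation(fine_spec)
  if (spec$kind == "radial_gaussian_contraction") {
    fld <- make_field0(spec, fine_seg, ctr)
  } else {
    # the random field is defined on the coarse grid; resample it
    coarse <- make_field0(spec, grid, ctr)
    fld <- resample_field(coarse, fine_seg)
  }
  jm <- jacobian_map(fld)
  v_fu <- integrate_jacobian(jm, fine_seg)
  pvc(voxel_count_volume(fine_seg), v_fu)
}

make_field0 <- function(spec, grid, ctr) {
  u <- with_seed(spec$seed,
                 field_vectors(spec, dim(grid$data), grid$affine, ctr))
  displacement_field(u, affine = grid$affine,
                     direction = "baseline_to_followup")
}

# Trilinearly resample a displacement field onto another volume's lattice.
resample_field <- function(field, target) {
  d <- dim(target$data)
  pts <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  w <- voxel_to_world(pts, target$affine)
  u <- suppressMessages(sample_displacement(field, w))
  displacement_field(array(u, c(d, 3)), affine = target$affine,
                     direction = field$direction)
}
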