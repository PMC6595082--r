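# Displacement sampling, mesh warping, Jacobian maps, and the equivalence of
# the mesh and Jacobian volumetry routes.

test_that("trilinear sampling reproduces constant and linear fields exactly", {
  seg <- make_segmentation(small_ellipsoid_spec())
  zero <- make_field(field_spec("zero"), seg, ground_truth = FALSE)
  pts <- rbind(c(5.3, 6.1, 7.9), c(10, 10, 10), c(2.5, 3.5, 4.5))
  expect_equal(sample_displacement(zero, pts), matrix(0, 3, 3),
               ignore_attr = TRUE)

  const <- make_field(field_spec("translation", shift = c(1, 2, 3)), seg,
                      ground_truth = FALSE)
  expect_equal(sample_displacement(const, pts),
               matrix(c(1, 2, 3), 3, 3, byrow = TRUE), ignore_attr = TRUE,
               tolerance = 1e-12)

  # u(x) = 0.1 * (x - c): linear, so trilinear interpolation is exact off-grid
  lin <- make_field(field_spec("uniform_scale", scale = rep(1.1, 3)),
                    seg, ground_truth = FALSE)
  off <- rbind(c(7.25, 9.75, 11.4))
  got <- sample_displacement(lin, off)
  ctr <- longivol:::field_center(field_spec("uniform_scale"), seg)
  expect_equal(as.vector(got), 0.1 * (as.vector(off) - ctr), tolerance = 1e-10)

  expect_error(sample_displacement(zero, rbind(c(NA, 0, 0))), "non-finite")
})

test_that("out-of-domain samples get zero displacement with a logged count", {
  seg <- make_segmentation(small_ellipsoid_spec())
  const <- make_field(field_spec("translation", shift = c(1, 1, 1)), seg,
                      ground_truth = FALSE)
  pts <- rbind(c(-50, 0, 0), c(8, 8, 8))
  expect_message(u <- sample_displacement(const, pts), "outside field domain")
  expect_equal(u[1, ], c(0, 0, 0))
  expect_equal(u[2, ], c(1, 1, 1))
  expect_equal(attr(u, "n_outside"), 1L)
})

test_that("warping preserves connectivity and tracks the field exactly", {
  seg <- make_segmentation(small_ellipsoid_spec())
  mesh <- extract_mesh(seg)
  v0 <- mesh_volume(mesh)

  same <- warp_mesh(mesh, make_field(field_spec("zero"), seg, ground_truth = FALSE))
  expect_equal(same$vertices, mesh$vertices)
  expect_identical(same$faces, mesh$faces)

  shifted <- warp_mesh(mesh, make_field(field_spec("translation", shift = c(2, 1, 0)),
                                        seg, ground_truth = FALSE))
  expect_equal(mesh_volume(shifted) / v0, 1, tolerance = 1e-9)

  s <- 0.983
  shrunk <- warp_mesh(mesh, make_field(field_spec("uniform_scale", scale = rep(s, 3)),
                                       seg, ground_truth = FALSE))
  expect_equal(mesh_volume(shrunk) / v0, s^3, tolerance = 1e-12)
  expect_equal(pvc(v0, mesh_volume(shrunk)), (s^3 - 1) * 100, tolerance = 1e-9)

  wrongdir <- make_field(field_spec("zero"), seg, ground_truth = FALSE)
  wrongdir$direction <- "followup_to_baseline"
  expect_error(warp_mesh(mesh, wrongdir), "baseline_to_followup")

  # a mesh far outside the field domain must be refused, not silently frozen
  far <- apply_affine(mesh, rbind(cbind(diag(3), c(500, 0, 0)), c(0, 0, 0, 1)))
  expect_error(suppressMessages(warp_mesh(far, same_field <- make_field(
    field_spec("translation", shift = c(1, 0, 0)), seg, ground_truth = FALSE))),
    "mesh escapes field")
})

test_that("Jacobian maps are exact for affine fields and clean for zero", {
  seg <- make_segmentation(small_ellipsoid_spec())
  jz <- jacobian_map(make_field(field_spec("zero"), seg, ground_truth = FALSE))
  expect_equal(max(abs(jz$det - 1)), 0, tolerance = 1e-14)
  expect_equal(jz$n_nonpositive, 0L)

  s <- 0.983
  js <- jacobian_map(make_field(field_spec("uniform_scale", scale = rep(s, 3)),
                                seg, ground_truth = FALSE))
  # linear field: central and one-sided second-order stencils are both exact
  expect_equal(max(abs(js$det - s^3)), 0, tolerance = 1e-12)
})

test_that("Jacobian maps refine towards the half-spacing recomputation", {
  # fixed contraction centre so the coarse and fine grids see the same field
  spec <- field_spec("radial_gaussian_contraction", k = 0.03, sigma = 9,
                     center = c(12.5, 10.5, 9.5))
  coarse_seg <- make_segmentation(small_ellipsoid_spec(spacing = 1))
  fine_seg <- make_segmentation(small_ellipsoid_spec(spacing = 0.5))
  jc <- jacobian_map(make_field(spec, coarse_seg, ground_truth = FALSE))
  jf <- jacobian_map(make_field(spec, fine_seg, ground_truth = FALSE))
  # compare on the coarse interior lattice: coarse voxel (i,j,k) sits at the
  # fine lattice point (2i, 2j, 2k) (same world origin, half spacing)
  d <- dim(jc$det)
  ii <- 2:(d[1] - 1); jj <- 2:(d[2] - 1); kk <- 2:(d[3] - 1)
  diff <- jc$det[ii, jj, kk] - jf$det[2 * ii - 1, 2 * jj - 1, 2 * kk - 1]
  expect_lt(max(abs(diff)), 1e-3)
})

test_that("oblique-but-rotated grids are supported, sheared grids rejected", {
  arr <- array(0L, c(9, 9, 9)); arr[4:6, 4:6, 4:6] <- 1L
  rot <- rigid_affine(shift = c(0, 0, 0))
  seg <- label_volume(arr, affine = rot)
  s <- 0.98
  fld <- make_field(field_spec("uniform_scale", scale = rep(s, 3)), seg,
                    ground_truth = FALSE)
  jm <- jacobian_map(fld)
  expect_equal(max(abs(jm$det - s^3)), 0, tolerance = 1e-10)

  shear <- diag(4); shear[1, 2] <- 0.3
  sheared <- displacement_field(array(0, c(5, 5, 5, 3)), affine = shear)
  expect_error(jacobian_map(sheared), "oblique grid unsupported")
})

test_that("Jacobian integration reduces to counting for the zero field", {
  arr <- array(0L, c(8, 8, 8)); arr[2:6, 2:6, 2:5] <- 1L  # 100 voxels
  seg <- label_volume(arr)
  jm <- jacobian_map(make_field(field_spec("zero"), seg, ground_truth = FALSE))
  expect_equal(integrate_jacobian(jm, seg), 100)
  s <- 0.983
  jms <- jacobian_map(make_field(field_spec("uniform_scale", scale = rep(s, 3)),
                                 seg, ground_truth = FALSE))
  expect_equal(integrate_jacobian(jms, seg), 100 * s^3, tolerance = 1e-9)
  other <- label_volume(array(0L, c(4, 4, 4)))
  expect_error(integrate_jacobian(jm, other), "grid mismatch")
})

test_that("mesh and Jacobian routes agree on smooth fixtures", {
  fields <- list(field_spec("radial_gaussian_contraction", k = 0.02, sigma = 10),
                 field_spec("smooth_random", amplitude = 0.25, sigma = 8, seed = 4))
  for (fl in fields) {
    fx <- end_to_end_fixture(small_ellipsoid_spec(), fl, ground_truth = FALSE)
    m <- measure_volume_change(fx$seg, fx$field)
    expect_lt(abs(m$pvc_difference), 0.1)
  }
})

test_that("composed contractions atrophy more than either alone", {
  seg <- make_segmentation(small_ellipsoid_spec())
  mesh <- extract_mesh(seg)
  v0 <- mesh_volume(mesh)
  f1 <- make_field(field_spec("radial_gaussian_contraction", k = 0.02, sigma = 10),
                   seg, ground_truth = FALSE)
  f2 <- make_field(field_spec("radial_gaussian_contraction", k = 0.04, sigma = 12),
                   seg, ground_truth = FALSE)
  p1 <- pvc(v0, mesh_volume(warp_mesh(mesh, f1)))
  p2 <- pvc(v0, mesh_volume(warp_mesh(mesh, f2)))
  p12 <- pvc(v0, mesh_volume(warp_mesh(warp_mesh(mesh, f1), f2)))
  expect_lt(p12, p1)
  expect_lt(p12, p2)
})
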