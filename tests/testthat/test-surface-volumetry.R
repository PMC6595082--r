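# Mesh extraction, signed-tetrahedron volumetry, affine propagation, overlap.

test_that("a single voxel meshes to a closed octahedron of volume 1/6", {
  arr <- array(0L, c(5, 5, 5)); arr[3, 3, 3] <- 1L
  m <- extract_mesh(label_volume(arr))
  expect_true(mesh_is_closed(m))
  # hand enumeration: 8 incident cells, each a single corner triangle with
  # vertices at edge midpoints -> octahedron |x|+|y|+|z| <= 1/2, V = 4/3*(1/2)^3
  expect_equal(mesh_volume(m), 1 / 6, tolerance = 1e-12)
  expect_equal(nrow(m$faces), 8L)
  expect_equal(nrow(m$vertices), 6L)
})

test_that("empty and boundary-touching segmentations are handled", {
  expect_error(extract_mesh(label_volume(array(0L, c(4, 4, 4)))), "empty label")
  arr <- array(0L, c(3, 3, 3)); arr[1, 2, 2] <- 1L  # touches the x = 0 face
  expect_message(m <- extract_mesh(label_volume(arr)), "padded")
  expect_true(mesh_is_closed(m))
  expect_equal(mesh_volume(m), 1 / 6, tolerance = 1e-12)
})

test_that("digitized ellipsoid volume converges to the closed form", {
  ana <- 4 / 3 * pi * prod(c(12, 8, 6))
  errs <- sapply(c(2, 1, 0.5), function(sp) {
    m <- extract_mesh(make_segmentation(shape_spec(spacing = sp)))
    expect_true(mesh_is_closed(m))
    abs(mesh_volume(m) - ana)
  })
  expect_lt(errs[2] / ana, 0.02)          # within 2% at 1 mm
  expect_true(all(diff(errs) < 0))        # strictly shrinking with spacing
})

test_that("mesh volume is within one surface layer of the voxel count", {
  for (s in 1:3) {
    seg <- make_segmentation(shape_spec("perturbed_blob", seed = s))
    m <- extract_mesh(seg)
    expect_true(mesh_is_closed(m))
    layer <- surface_voxel_layer(seg)
    expect_lt(abs(mesh_volume(m) - voxel_count_volume(seg)), layer)
  }
})

test_that("signed-tetrahedron volume behaves like a volume", {
  cube <- unit_cube_mesh()
  expect_equal(mesh_volume(cube), 1, tolerance = 1e-12)
  # orientation antisymmetry: flipping all faces negates the signed sum
  flipped <- triangle_mesh(cube$vertices, cube$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped, signed = TRUE), -1, tolerance = 1e-12)
  expect_warning(v <- mesh_volume(flipped), "negative signed volume")
  expect_equal(v, 1, tolerance = 1e-12)
  # translation invariance
  moved <- unit_cube_mesh(origin = c(100, -50, 3))
  expect_equal(mesh_volume(moved), 1, tolerance = 1e-9)
  # open surfaces are rejected
  open_mesh <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(mesh_volume(open_mesh), "open surface")
})

test_that("affine propagation scales volume by the determinant", {
  cube <- unit_cube_mesh()
  ident <- apply_affine(cube, diag(4))
  expect_identical(ident$vertices, cube$vertices)
  expect_equal(mesh_volume(apply_affine(cube, diag(c(2, 2, 2, 1)))), 8,
               tolerance = 1e-12)
  rigid <- apply_affine(cube, rigid_affine())
  expect_equal(mesh_volume(rigid), 1, tolerance = 1e-9)
  # property: random invertible affines on a digitized blob
  seg <- make_segmentation(small_ellipsoid_spec())
  m <- extract_mesh(seg)
  v0 <- mesh_volume(m, warn_negative = FALSE)
  set.seed(42)
  for (rep in 1:5) {
    a <- random_invertible_affine()
    v1 <- mesh_volume(apply_affine(m, a), warn_negative = FALSE)
    expect_equal(v1 / v0, abs(det(a[1:3, 1:3])), tolerance = 1e-9)
  }
  expect_error(apply_affine(cube, matrix(0, 4, 4)), "last row|singular")
})

test_that("Jaccard index matches counting", {
  g <- array(0L, c(4, 4, 2))
  a <- g; a[1:2, 1, 1] <- 1L
  b <- g; b[2:3, 1, 1] <- 1L
  va <- label_volume(a); vb <- label_volume(b)
  expect_equal(jaccard_index(va, vb), 1 / 3)
  expect_equal(jaccard_index(va, vb), jaccard_index(vb, va))
  expect_equal(jaccard_index(va, va), 1)
  d <- g; d[4, 4, 2] <- 1L
  expect_equal(jaccard_index(va, label_volume(d)), 0)
  empty <- label_volume(g)
  expect_error(jaccard_index(empty, empty), "undefined overlap")
  expect_error(jaccard_index(va, label_volume(array(0L, c(3, 3, 3)))),
               "identical grids")
})
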