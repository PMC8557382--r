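test_that("alpha = Inf reproduces the convex hull", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  hull <- alpha_shape(cube, alpha = Inf)
  expect_equal(hull$n_boundary_faces, 12)
  expect_equal(nrow(hull$vertices), 8)
  expect_equal(abs(mesh_signed_volume(orient_outward(hull))), 1,
               tolerance = 1e-12)

  # random point sets against the triple-enumeration hull oracle
  for (s in 1:3) {
    pts <- with_seed(40 + s, matrix(rnorm(3 * 40), ncol = 3))
    mesh <- alpha_shape(pts, alpha = Inf)
    got <- sort(mesh_face_keys_in(mesh, pts))
    expect_equal(got, bf_hull_faces(pts))
  }
})

test_that("too small an alpha yields an explicit empty-shape error", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  # any tetrahedron on cube corners has circumradius >= sqrt(3)/2
  expect_error(alpha_shape(cube, alpha = 0.1), "empty alpha shape")
  expect_error(alpha_shape(cbind(runif(10), runif(10), 0), alpha = 1),
               "coplanar")
})

test_that("boundary faces match the brute-force alpha-shape enumeration", {
  # points on a torus shell: cavities appear at moderate alpha
  n <- 45
  pts <- with_seed(13, {
    u <- runif(n, 0, 2 * pi)
    v <- runif(n, 0, 2 * pi)
    R0 <- 1; r0 <- 0.4
    cbind((R0 + r0 * cos(v)) * cos(u),
          (R0 + r0 * cos(v)) * sin(u),
          r0 * sin(v))
  })
  for (alpha in c(0.6, 1.0, Inf)) {
    ref <- bf_alpha_boundary(pts, alpha)
    mesh <- alpha_shape(pts, alpha = alpha)
    expect_equal(sort(mesh_face_keys_in(mesh, pts)), ref)
  }
})

test_that("the kept-tetrahedron set grows monotonically with alpha", {
  pts <- with_seed(14, matrix(runif(3 * 400), ncol = 3))
  kept <- vapply(c(0.12, 0.2, 0.5, 1, Inf), function(a)
    alpha_shape(pts, alpha = a)$n_tetrahedra_kept, numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("alpha-shape normals point outward for convex sets", {
  pts <- with_seed(17, matrix(rnorm(3 * 200), ncol = 3))
  hull <- alpha_shape(pts, alpha = Inf)
  ctr <- colMeans(hull$vertices)
  d <- sweep(hull$face_centroids, 2, ctr)
  expect_true(all(rowSums(hull$face_normals * d) > 0))
  # and agree with the divergence theorem
  expect_gt(mesh_signed_volume(hull), 0)
})

test_that("orient_outward flips inward faces and is idempotent", {
  ico <- icosphere_mesh(radius = 2, center = c(5, 5, 5))
  flipped <- triangle_mesh(ico$vertices, ico$faces[, c(1, 3, 2)])
  fixed <- orient_outward(flipped, interior_reference = c(5, 5, 5))
  radial <- sweep(fixed$face_centroids, 2, c(5, 5, 5))
  expect_true(all(rowSums(fixed$face_normals * radial) > 0))
  again <- orient_outward(fixed)
  expect_identical(again$faces, fixed$faces)
  # signed volume of the oriented icosphere is positive and near 4/3 pi r^3
  expect_gt(mesh_signed_volume(fixed), 0)
  expect_equal(mesh_signed_volume(fixed), 4 / 3 * pi * 8, tolerance = 0.15)
})

test_that("Delaunay tetrahedra tile the hull and have empty circumspheres", {
  pts <- with_seed(18, matrix(runif(3 * 300), ncol = 3))
  dt <- delaunay_tetrahedra(pts)
  cs <- bf_circumspheres(pts, dt$tets)
  expect_equal(cs$radius, dt$circumradius, tolerance = 1e-9)
  expect_equal(cs$volume, dt$volume, tolerance = 1e-9)
  # spot-check circumsphere emptiness on 50 random tetrahedra
  idx <- with_seed(19, sample(nrow(dt$tets), 50))
  for (r in idx) {
    d2 <- colSums((t(pts) - cs$centre[r, ])^2)
    d2[dt$tets[r, ]] <- Inf
    expect_true(all(d2 > cs$radius[r]^2 - 1e-9))
  }
})
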