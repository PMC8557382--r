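test_that("two-way NN collects exactly the nearest-neighbour targets", {
  a <- matrix(c(0, 0, 0), 1)
  b <- matrix(c(1, 0, 0), 1)
  nn <- two_way_nn(a, b)
  expect_equal(nn$a_idx, 1)
  expect_equal(nn$b_idx, 1)

  # two parallel 10 x 10 grids 1 m apart: every point is someone's NN
  g <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  A <- cbind(g, 0)
  B <- cbind(g, 1)
  nn <- two_way_nn(A, B)
  expect_equal(nn$a_idx, 1:100)
  expect_equal(nn$b_idx, 1:100)

  expect_error(two_way_nn(A, B + 100, max_dist = 0.1), "no interaction")
})

test_that("spatial-index NN selection matches the brute-force search", {
  for (s in c(2, 3)) {
    n <- c(600, 2000)[s - 1]
    pts <- with_seed(s, list(a = matrix(rnorm(3 * n), ncol = 3),
                             b = matrix(rnorm(3 * n, mean = 1), ncol = 3)))
    nn <- two_way_nn(pts$a, pts$b)
    expect_equal(nn$a_idx, sort(unique(bf_nn_index(pts$a, pts$b))))
    expect_equal(nn$b_idx, sort(unique(bf_nn_index(pts$b, pts$a))))
  }
})

test_that("oriented box axes follow the centroid line with tight extents", {
  # crowns with xy centroids (0,0) and (2,0); near set given explicitly
  A <- cbind(runif(50, -0.5, 0.5), runif(50, -0.5, 0.5), runif(50, 5, 15))
  A <- sweep(A, 2, colMeans(A) * c(1, 1, 0))  # centre xy exactly at 0
  B <- sweep(A, 2, c(2, 0, 0), "+")
  near <- list(a_near = rbind(c(0.8, -1, 5), c(1.2, 1, 15)),
               b_near = rbind(c(1.0, 0, 10)))
  box <- oriented_box(A, B, near)
  expect_equal(box$box_axes, diag(3), tolerance = 1e-12)
  expect_equal(box$box_center, c(1, 0, 10))
  expect_equal(box$box_extents, c(0.2, 1, 5))

  # padding widens the two horizontal extents only
  boxp <- oriented_box(A, B, near, padding = 0.5)
  expect_equal(boxp$box_extents, c(0.7, 1.5, 5))

  # rotational equivariance about z
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- function(m) m %*% R
  boxr <- oriented_box(rot(A), rot(B),
                       list(a_near = rot(near$a_near),
                            b_near = rot(near$b_near)))
  expect_equal(boxr$box_extents, box$box_extents, tolerance = 1e-9)
  expect_equal(unname(boxr$box_axes), unname(box$box_axes %*% R),
               tolerance = 1e-9)

  expect_error(oriented_box(A, A, near), "coincident")
})

test_that("box symmetry: swapping the crowns reverses the first axis", {
  p <- make_pair(gap = 0.5, seed = 5, crown_points = 3000, stem_points = 200)
  sa <- segment_crown(p$a)$crown
  sb <- segment_crown(p$b)$crown
  near <- two_way_nn(sa, sb)
  b1 <- oriented_box(sa, sb, near)
  b2 <- oriented_box(sb, sa, list(a_near = near$b_near,
                                  b_near = near$a_near))
  expect_equal(b2$box_axes[1, ], -b1$box_axes[1, ], tolerance = 1e-12)
  expect_equal(b2$box_extents, b1$box_extents, tolerance = 1e-9)
  expect_equal(b2$box_center, b1$box_center, tolerance = 1e-9)
})

test_that("clipping keeps exactly the points inside the box (closed faces)", {
  p <- make_pair(gap = 0.4, seed = 5, crown_points = 4000, stem_points = 300)
  sa <- segment_crown(p$a)$crown
  sb <- segment_crown(p$b)$crown
  zone <- interaction_zone(sa, sb)
  ref_a <- bf_in_box(sa$points, zone$box_center, zone$box_axes,
                     zone$box_extents)
  ref_b <- bf_in_box(sb$points, zone$box_center, zone$box_axes,
                     zone$box_extents)
  expect_equal(unname(zone$a_clip$points), unname(sa$points[ref_a, ]))
  expect_equal(unname(zone$b_clip$points), unname(sb$points[ref_b, ]))
  # every near point lies inside the box
  expect_true(all(bf_in_box(rbind(zone$a_near, zone$b_near),
                            zone$box_center, zone$box_axes,
                            zone$box_extents)))
  # vertical span equals the near set's z range
  nz <- rbind(zone$a_near, zone$b_near)[, 3]
  expect_equal(zone$box_center[3] - zone$box_extents[3], min(nz))
  expect_equal(zone$box_center[3] + zone$box_extents[3], max(nz))

  # a point exactly on a box face is kept
  region <- structure(list(box_center = c(0, 0, 0), box_axes = diag(3),
                           box_extents = c(1, 1, 1),
                           a_near = matrix(0, 1, 3),
                           b_near = matrix(0, 1, 3)),
                      class = "interaction_region")
  A <- rbind(c(1, 0, 0), c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0.5), c(2, 0, 0))
  B <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0), c(0, 0, 0.1))
  out <- clip_to_region(region, A, B)
  expect_equal(out$a_clip$n, 4)  # the face point is in, (2,0,0) is out
  expect_equal(out$b_clip$n, 4)  # box encloses all of B

  # too few points for a surface
  expect_error(clip_to_region(region, A[1:5, ], B[1:3, ]),
               "insufficient points")
})
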