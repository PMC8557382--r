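test_that("face matching selects nearest-centroid targets both ways", {
  t1 <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(1:3, 1))
  t2 <- triangle_mesh(rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1)),
                      matrix(1:3, 1))
  mp <- match_faces(t1, t2)
  expect_equal(mp$j, 1)
  expect_equal(mp$k, 1)
  expect_equal(unname(mp$uv_pairs[1, 1:2]), c(1, 1))

  u <- plate_mesh(n = 10, z = 0, normal = 1)
  v <- plate_mesh(n = 10, z = 0.1, normal = -1)
  mp <- match_faces(u, v)
  # brute-force nearest-centroid oracle
  nn_uv <- bf_nn_index(v$face_centroids, u$face_centroids)
  nn_vu <- bf_nn_index(u$face_centroids, v$face_centroids)
  expect_equal(unname(mp$uv_pairs[, "u_face"]), sort(unique(nn_vu)))
  expect_equal(unname(mp$uv_pairs[, "v_face"]),
               nn_uv[sort(unique(nn_vu))])
  expect_equal(unname(mp$vu_pairs[, "v_face"]), sort(unique(nn_uv)))

  far <- plate_mesh(n = 10, z = 10, normal = -1)
  expect_error(match_faces(u, far, max_dist = 1), "no facing surface")
})

test_that("Sc sign semantics: mating plates +1, interpenetrating -1, bounded", {
  u <- plate_mesh(n = 10, z = 0, normal = 1)    # outward normal toward V
  v <- plate_mesh(n = 10, z = 0.1, normal = -1) # outward normal toward U
  r <- sc_score(u, v)
  expect_equal(r$sc, 1)
  expect_equal(r$mean_uv, 1)
  expect_equal(r$mean_vu, 1)

  v_flip <- plate_mesh(n = 10, z = 0.1, normal = 1)
  r2 <- sc_score(u, v_flip)
  expect_equal(r2$sc, -1)

  # two icospheres with a small gap: convex-convex coincidence, 0 < Sc < 1
  s1 <- icosphere_mesh(radius = 1, center = c(0, 0, 0))
  s2 <- icosphere_mesh(radius = 1, center = c(2.05, 0, 0))
  r3 <- sc_score(s1, s2)
  expect_gt(r3$sc, 0)
  expect_lt(r3$sc, 1)
  # independent dot-product recomputation from the matched pairs
  mp <- match_faces(s1, s2)
  ref_uv <- mean(vapply(seq_len(mp$j), function(i)
    sum(s1$face_normals[mp$uv_pairs[i, 1], ] *
        -s2$face_normals[mp$uv_pairs[i, 2], ]), numeric(1)))
  ref_vu <- mean(vapply(seq_len(mp$k), function(i)
    sum(s2$face_normals[mp$vu_pairs[i, 1], ] *
        -s1$face_normals[mp$vu_pairs[i, 2], ]), numeric(1)))
  expect_equal(r3$sc, (ref_uv + ref_vu) / 2, tolerance = 1e-12)
  expect_equal(r3$sc, (r3$mean_uv + r3$mean_vu) / 2, tolerance = 1e-12)
})

test_that("non-unit normals are rejected", {
  u <- plate_mesh(n = 2)
  v <- plate_mesh(n = 2, z = 0.1, normal = -1)
  v$face_normals <- v$face_normals * 2
  expect_error(sc_score(u, v), "unit")
})

test_that("pair_sc orders shy above overlapping and is degenerate-safe", {
  shy <- make_pair(gap = 0.3, seed = 21)
  ovl <- make_pair(gap = -1.0, seed = 21)
  r_shy <- pair_sc(shy$a, shy$b)
  r_ovl <- pair_sc(ovl$a, ovl$b)
  expect_gt(r_shy$sc, r_ovl$sc)
  expect_true(abs(r_shy$sc) <= 1 && abs(r_ovl$sc) <= 1)
  expect_true(abs(r_shy$mean_uv) <= 1 && abs(r_shy$mean_vu) <= 1)

  # same cloud twice: coincident centroids, named stage in the error
  expect_error(pair_sc(shy$a, shy$a), "interaction_zone")
})

test_that("alpha sweep is consistent with single runs and records misses", {
  p <- make_pair(gap = 0.5, seed = 23, crown_points = 6000,
                 stem_points = 400)
  sw <- alpha_sweep(p$a, p$b)
  expect_equal(nrow(sw), 8)
  expect_true(all(diff(sw$alpha) > 0))
  expect_true(all(abs(sw$sc[sw$ok]) <= 1))

  one <- alpha_sweep(p$a, p$b, alphas = 1.0)
  full <- pair_sc(p$a, p$b, alpha = 1.0)
  expect_equal(one$sc, full$sc, tolerance = 1e-12)

  # an alpha far below the point spacing is recorded, not fatal
  tiny <- alpha_sweep(p$a, p$b, alphas = c(0.001, 1))
  expect_false(tiny$ok[1])
  expect_match(tiny$note[1], "empty alpha shape")
  expect_true(tiny$ok[2])

  expect_error(alpha_sweep(p$a, p$b, alphas = c(1, 0.5)),
               "strictly increasing")
})

test_that("a shallowly overlapping pair shows the rising limb in alpha", {
  # peripheral interdigitation: small alpha hugs the contact relief and
  # scores lower than the stable band around alpha = 1
  p <- make_pair(gap = -0.3, seed = 23)
  sw <- alpha_sweep(p$a, p$b, alphas = c(0.2, 1.0))
  expect_true(all(sw$ok))
  expect_lte(sw$sc[1], sw$sc[2])
})

test_that("Sc decreases as crown interpenetration deepens (seed-averaged)", {
  depths <- c(-0.1, -0.7, -1.4, -2.0)
  curve <- vapply(depths, function(g)
    mean(vapply(1:3, function(s) {
      p <- make_pair(gap = g, seed = 100 + s)
      pair_sc(p$a, p$b)$sc
    }, numeric(1))), numeric(1))
  expect_true(all(diff(curve) < 0))
})

test_that("sweep_summary averages per alpha and counts misses", {
  one <- data.frame(alpha = 1, sc = 0.42, ok = TRUE)
  s1 <- sweep_summary(one)
  expect_equal(s1$mean_sc, 0.42)
  expect_equal(s1$median_sc, 0.42)

  rows <- data.frame(alpha = rep(1, 3), sc = c(0.2, 0.4, 0.9))
  s2 <- sweep_summary(rows)
  expect_equal(s2$mean_sc, 0.5)
  expect_equal(s2$median_sc, 0.4)

  long <- with_seed(31, data.frame(
    pair_id = rep(1:10, each = 2),
    alpha = rep(c(0.5, 1), 10),
    sc = runif(20, -1, 1)))
  long$sc[3] <- NA  # one recorded miss
  s3 <- sweep_summary(long)
  for (a in c(0.5, 1)) {
    v <- long$sc[long$alpha == a]
    expect_equal(s3$mean_sc[s3$alpha == a], mean(v, na.rm = TRUE))
    expect_equal(s3$median_sc[s3$alpha == a], median(v, na.rm = TRUE))
  }
  expect_equal(sum(s3$n_missing), 1)
})
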