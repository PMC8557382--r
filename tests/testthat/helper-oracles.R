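# Independent brute-force oracles used to validate the geometric core.
# These deliberately avoid the package's own algorithms: the hull and
# alpha-shape oracles work straight from the definitions by exhaustive
# enumeration, the NN oracle from the full distance matrix.

# nearest-neighbour index in `data` of every row of `query`, O(n * m)
bf_nn_index <- function(data, query) {
  apply(query, 1, function(q) {
    which.min(colSums((t(data) - q)^2))
  })
}

# canonical string key of a face given by three vertex indices
face_key <- function(f) {
  apply(f, 1, function(r) paste(sort(r), collapse = "-"))
}

# convex hull facets by triple enumeration: a triple is a hull facet iff
# all remaining points lie weakly on one side of its plane (points must
# be in generic position so facets are triangles)
bf_hull_faces <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  trip <- t(combn(n, 3))
  keys <- character(0)
  for (r in seq_len(nrow(trip))) {
    i <- trip[r, ]
    u <- pts[i[2], ] - pts[i[1], ]
    w <- pts[i[3], ] - pts[i[1], ]
    nrm <- c(u[2] * w[3] - u[3] * w[2],
             u[3] * w[1] - u[1] * w[3],
             u[1] * w[2] - u[2] * w[1])
    if (sqrt(sum(nrm^2)) < tol) next
    s <- (pts[-i, , drop = FALSE] -
            matrix(pts[i[1], ], n - 3, 3, byrow = TRUE)) %*% nrm
    if (all(s <= tol) || all(s >= -tol))
      keys <- c(keys, paste(sort(i), collapse = "-"))
  }
  sort(unique(keys))
}

# circumcentres and radii of the tetrahedra given as an m x 4 index matrix
bf_circumspheres <- function(pts, tets) {
  a <- pts[tets[, 1], , drop = FALSE]
  b <- pts[tets[, 2], , drop = FALSE]
  c_ <- pts[tets[, 3], , drop = FALSE]
  d <- pts[tets[, 4], , drop = FALSE]
  ba <- b - a; ca <- c_ - a; da <- d - a
  det <- ba[, 1] * (ca[, 2] * da[, 3] - ca[, 3] * da[, 2]) -
         ba[, 2] * (ca[, 1] * da[, 3] - ca[, 3] * da[, 1]) +
         ba[, 3] * (ca[, 1] * da[, 2] - ca[, 2] * da[, 1])
  r1 <- rowSums(ba^2) / 2; r2 <- rowSums(ca^2) / 2; r3 <- rowSums(da^2) / 2
  cx <- (r1 * (ca[, 2] * da[, 3] - ca[, 3] * da[, 2]) -
         ba[, 2] * (r2 * da[, 3] - ca[, 3] * r3) +
         ba[, 3] * (r2 * da[, 2] - ca[, 2] * r3)) / det
  cy <- (ba[, 1] * (r2 * da[, 3] - ca[, 3] * r3) -
         r1 * (ca[, 1] * da[, 3] - ca[, 3] * da[, 1]) +
         ba[, 3] * (ca[, 1] * r3 - r2 * da[, 1])) / det
  cz <- (ba[, 1] * (ca[, 2] * r3 - r2 * da[, 2]) -
         ba[, 2] * (ca[, 1] * r3 - r2 * da[, 1]) +
         r1 * (ca[, 1] * da[, 2] - ca[, 2] * da[, 1])) / det
  centre <- a + cbind(cx, cy, cz)
  list(centre = centre,
       radius = sqrt(cx^2 + cy^2 + cz^2),
       volume = abs(det) / 6)
}

# regularized alpha-shape boundary faces straight from the definition:
# enumerate every 4-subset, keep it when its circumsphere is empty
# (Delaunay) and its circumradius is at most alpha, then collect the
# faces incident to exactly one kept tetrahedron
bf_alpha_boundary <- function(pts, alpha, tol = 1e-9) {
  n <- nrow(pts)
  tets <- t(combn(n, 4))
  cs <- bf_circumspheres(pts, tets)
  ok <- is.finite(cs$radius) & cs$volume > 1e-12
  empty <- vapply(seq_len(nrow(tets)), function(r) {
    if (!ok[r]) return(FALSE)
    d2 <- colSums((t(pts) - cs$centre[r, ])^2)
    d2[tets[r, ]] <- Inf
    all(d2 > cs$radius[r]^2 - tol)
  }, logical(1))
  kept <- tets[empty & cs$radius <= alpha + tol, , drop = FALSE]
  if (nrow(kept) == 0) return(character(0))
  faces <- rbind(kept[, c(2, 3, 4)], kept[, c(1, 3, 4)],
                 kept[, c(1, 2, 4)], kept[, c(1, 2, 3)])
  keys <- face_key(faces)
  sort(names(which(table(keys) == 1)))
}

# signed-plane containment check for a point in an oriented box
bf_in_box <- function(pts, center, axes, extents, tol = 1e-12) {
  local <- sweep(pts %*% t(axes), 2, as.numeric(center %*% t(axes)))
  abs(local[, 1]) <= extents[1] + tol &
    abs(local[, 2]) <= extents[2] + tol &
    abs(local[, 3]) <= extents[3] + tol
}

# icosphere: icosahedron subdivided once -> 42 vertices, 80 faces
icosphere_mesh <- function(radius = 1, center = c(0, 0, 0)) {
  t_ <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t_, 0), c(1, t_, 0), c(-1, -t_, 0), c(1, -t_, 0),
             c(0, -1, t_), c(0, 1, t_), c(0, -1, -t_), c(0, 1, -t_),
             c(t_, 0, -1), c(t_, 0, 1), c(-t_, 0, -1), c(-t_, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # one subdivision
  edge_mid <- new.env()
  vs <- v
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    if (!is.null(edge_mid[[key]])) return(edge_mid[[key]])
    m <- (vs[i, ] + vs[j, ]) / 2
    m <- m / sqrt(sum(m^2))
    vs <<- rbind(vs, m)
    edge_mid[[key]] <- nrow(vs)
    nrow(vs)
  }
  nf <- matrix(0L, 0, 3)
  for (r in seq_len(nrow(f))) {
    i <- f[r, 1]; j <- f[r, 2]; k <- f[r, 3]
    a <- midpoint(i, j); b <- midpoint(j, k); c_ <- midpoint(k, i)
    nf <- rbind(nf, c(i, a, c_), c(j, b, a), c(k, c_, b), c(a, b, c_))
  }
  crownshy::triangle_mesh(sweep(vs * radius, 2, center, "+"), nf)
}

# rotate a point cloud about the vertical axis
rotate_z <- function(cloud, angle_deg) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  point_cloud(cloud$points %*% R, tree_id = cloud$tree_id)
}

translate_cloud <- function(cloud, v) {
  point_cloud(sweep(cloud$points, 2, v, "+"), tree_id = cloud$tree_id)
}

# mesh face set as coordinate keys (robust to vertex re-indexing)
face_coord_keys <- function(mesh, digits = 9) {
  apply(mesh$faces, 1, function(f) {
    rows <- apply(mesh$vertices[f, , drop = FALSE], 1, function(p)
      paste(formatC(p, digits = digits, format = "g"), collapse = ","))
    paste(sort(rows), collapse = ";")
  })
}

# convert alpha-shape boundary faces to index keys in original point order
mesh_face_keys_in <- function(mesh, pts, tol = 1e-9) {
  idx <- bf_nn_index(pts, mesh$vertices)
  stopifnot(max(abs(mesh$vertices - pts[idx, , drop = FALSE])) < tol)
  face_key(matrix(idx[mesh$faces], ncol = 3))
}

guyana_trees <- function() {
  read_tree_metrics(system.file("extdata", "guyana_tree_metrics.csv",
                                package = "crownshy"))
}

guyana_pairs <- function() {
  utils::read.csv(system.file("extdata", "guyana_pairs.csv",
                              package = "crownshy"))
}
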