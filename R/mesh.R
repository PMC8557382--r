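#' Construct a triangle mesh
#'
#' The mesh container used for alpha-shape crown surfaces: vertices,
#' triangular faces, per-face centroids and unit normals.  Normals follow
#' the right-hand rule on the face winding; [orient_outward()] or the
#' owner-tetrahedron information in [alpha_shape()] make them outward.
#'
#' @param vertices n x 3 numeric matrix (metres).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param alpha the alpha value (metres, possibly `Inf`) the surface was
#'   built with, or `NA` for meshes from other sources.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `face_centroids`, `face_normals`, `alpha`.
#' @export
triangle_mesh <- function(vertices, faces, alpha = NA_real_) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 3) stop("vertices must be n x 3")
  f <- as.matrix(faces)
  storage.mode(f) <- "integer"
  if (ncol(f) != 3) stop("faces must be m x 3")
  if (nrow(f) < 1) stop("mesh has no faces")
  if (min(f) < 1 || max(f) > nrow(v)) stop("face indices out of range")
  colnames(v) <- c("x", "y", "z")
  geo <- face_geometry(v, f)
  if (any(geo$area < .Machine$double.eps))
    stop("mesh contains zero-area faces")
  structure(list(vertices = v, faces = f,
                 face_centroids = geo$centroids,
                 face_normals = geo$normals,
                 alpha = alpha),
            class = "triangle_mesh")
}

face_geometry <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cen <- (a + b + c_) / 3
  e1 <- b - a
  e2 <- c_ - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  list(centroids = cen,
       normals = nrm / pmax(len, .Machine$double.xmin),
       area = len / 2)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.finite(x$alpha)) sprintf(", alpha = %g m", x$alpha)
              else if (is.infinite(x$alpha)) ", alpha = Inf (convex hull)"
              else ""))
  invisible(x)
}

#' Orient mesh face normals outward
#'
#' Flips every face whose normal points toward the reference interior
#' point rather than away from it.  Alpha-shape surfaces from
#' [alpha_shape()] are already oriented per owning tetrahedron; this
#' reference-point variant serves meshes from other sources and is
#' idempotent on already-outward meshes.
#'
#' @param mesh a [triangle_mesh()].
#' @param interior_reference length-3 point assumed inside the surface;
#'   defaults to the vertex centroid.
#' @return The re-oriented `triangle_mesh`.
#' @export
orient_outward <- function(mesh, interior_reference = NULL) {
  if (!inherits(mesh, "triangle_mesh")) stop("'mesh' must be a triangle_mesh")
  ref <- if (is.null(interior_reference)) colMeans(mesh$vertices)
         else as.numeric(interior_reference)
  if (length(ref) != 3) stop("interior_reference must be a 3-vector")
  d <- mesh$face_centroids - matrix(ref, nrow(mesh$faces), 3, byrow = TRUE)
  flip <- rowSums(mesh$face_normals * d) < 0
  if (any(flip)) {
    f <- mesh$faces
    f[flip, c(2, 3)] <- f[flip, c(3, 2)]
    mesh <- triangle_mesh(mesh$vertices, f, alpha = mesh$alpha)
  }
  mesh
}

#' Signed volume enclosed by an oriented surface
#'
#' Divergence-theorem sum over faces; positive for a closed surface with
#' outward normals.
#'
#' @param mesh a [triangle_mesh()].
#' @return signed volume in cubic metres.
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Flat triangulated plate mesh
#'
#' A regular grid on a horizontal square, triangulated, with all face
#' normals pointing along +z or -z.  Used as an analytic calibration
#' surface for [sc_score()]: two plates facing each other are the perfect
#' complementarity limit (Sc = 1), and flipping one plate's normals gives
#' the full-opposition limit (Sc = -1).
#'
#' @param n grid subdivisions per side (the plate has `2 n^2` faces).
#' @param size side length in metres.
#' @param z plate height in metres.
#' @param normal `+1` for normals along +z, `-1` for -z.
#' @param origin xy position of the lower-left corner.
#' @return A [triangle_mesh()].
#' @export
plate_mesh <- function(n = 10, size = 1, z = 0, normal = 1,
                       origin = c(0, 0)) {
  stopifnot(n >= 1, size > 0, normal %in% c(-1, 1))
  s <- seq(0, size, length.out = n + 1)
  g <- expand.grid(x = s + origin[1], y = s + origin[2])
  v <- cbind(g$x, g$y, z)
  id <- function(i, j) (j - 1L) * (n + 1L) + i  # i, j in 1..n+1
  f <- matrix(0L, 2 * n * n, 3)
  k <- 1L
  for (j in 1:n) for (i in 1:n) {
    # counter-clockwise seen from +z => normal +z
    f[k, ] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
    f[k + 1L, ] <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
    k <- k + 2L
  }
  if (normal < 0) f[, c(2, 3)] <- f[, c(3, 2)]
  triangle_mesh(v, f)
}
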