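#' 3-D Delaunay tetrahedralization
#'
#' Incremental (Bowyer-Watson) Delaunay tetrahedralization of a 3-D
#' point set, the substrate of the alpha-shape surface.  Exposed mainly
#' for inspection; most users want [alpha_shape()].
#'
#' @param points a [point_cloud()] or n x 3 matrix (at least 4
#'   non-coplanar points; exact duplicate points are removed).
#' @return A list with `tets` (m x 4 matrix of 1-based indices into
#'   `points`, after duplicate removal), `circumradius` and `volume`
#'   per tetrahedron (metres and cubic metres), and `points` (the
#'   deduplicated coordinates).
#' @export
delaunay_tetrahedra <- function(points) {
  pts <- as_xyz(points)
  dup <- duplicated(pts)
  if (any(dup)) pts <- pts[!dup, , drop = FALSE]
  if (nrow(pts) < 4) stop("need at least 4 distinct points")
  if (points_rank(pts) < 3)
    stop("degenerate input: points are coplanar")
  dt <- .delaunay3d_cpp(pts)
  if (nrow(dt$tets) == 0) stop("degenerate input: no tetrahedra produced")
  dt$points <- pts
  dt
}

#' Regularized 3-D alpha shape of a point set
#'
#' Computes the Delaunay tetrahedralization, keeps the tetrahedra whose
#' circumsphere radius is at most `alpha` (metres), and returns the
#' boundary of their union: the faces incident to exactly one kept
#' tetrahedron, wound so that normals point away from the kept side.
#' `alpha = Inf` gives the convex hull.  Singular (dangling) faces and
#' edges of the full alpha complex are excluded -- the surface is always
#' the shell of a solid, so every face has a well-defined outward
#' normal, which the complementarity statistic requires.
#'
#' Near-degenerate tetrahedra (volume below `min_volume`) are dropped
#' before the circumradius test; their circumradii are numerically
#' unreliable and can explode.
#'
#' @param points a [point_cloud()] or n x 3 matrix.
#' @param alpha probe sphere radius in metres, or `Inf`.  Default 1 m,
#'   inside the stable band (roughly 1-2 m) for metre-scale crowns.
#' @param tol absolute tolerance on the circumradius comparison
#'   (`circumradius <= alpha + tol` keeps the tetrahedron).
#' @param min_volume tetrahedra smaller than this (cubic metres) are
#'   treated as degenerate and never kept.
#' @return A `triangle_mesh` with additional class `alpha_shape` and
#'   extra elements `n_tetrahedra_kept` and `n_boundary_faces`.
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' hull <- alpha_shape(cube, alpha = Inf)
#' hull$n_boundary_faces  # 12: the convex hull of a cube
#' @export
alpha_shape <- function(points, alpha = 1, tol = 1e-12, min_volume = 1e-12) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && (alpha > 0)))
    stop("alpha must be a positive number or Inf")
  dt <- delaunay_tetrahedra(points)
  kept <- dt$volume > min_volume & dt$circumradius <= alpha + tol
  if (!any(kept))
    stop(sprintf(
      "empty alpha shape: no tetrahedron has circumradius <= %g m (min is %g m)",
      alpha, suppressWarnings(min(dt$circumradius[dt$volume > min_volume]))))
  tets <- dt$tets[kept, , drop = FALSE]
  m <- nrow(tets)

  # faces of kept tets; slot i holds the face opposite vertex i
  fv <- rbind(tets[, c(2, 3, 4), drop = FALSE],
              tets[, c(1, 3, 4), drop = FALSE],
              tets[, c(1, 2, 4), drop = FALSE],
              tets[, c(1, 2, 3), drop = FALSE])
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  lo <- pmin(fv[, 1], fv[, 2], fv[, 3])
  hi <- pmax(fv[, 1], fv[, 2], fv[, 3])
  mid <- fv[, 1] + fv[, 2] + fv[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  boundary <- !(key %in% key[duplicated(key)])
  if (!any(boundary)) stop("alpha shape has no boundary faces")
  bf <- fv[boundary, , drop = FALSE]
  bopp <- opp[boundary]

  # wind each face so its normal points away from the kept tet's
  # opposite vertex (i.e. outward from the solid)
  v <- dt$points
  e1 <- v[bf[, 2], , drop = FALSE] - v[bf[, 1], , drop = FALSE]
  e2 <- v[bf[, 3], , drop = FALSE] - v[bf[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  toward_opp <- v[bopp, , drop = FALSE] - v[bf[, 1], , drop = FALSE]
  flip <- rowSums(nrm * toward_opp) > 0
  bf[flip, c(2, 3)] <- bf[flip, c(3, 2)]

  # compact to referenced vertices
  used <- sort(unique(as.integer(bf)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  mesh <- triangle_mesh(v[used, , drop = FALSE],
                        matrix(remap[bf], ncol = 3),
                        alpha = alpha)
  mesh$n_tetrahedra_kept <- m
  mesh$n_boundary_faces <- nrow(bf)
  class(mesh) <- c("alpha_shape", class(mesh))
  mesh
}

#' @export
print.alpha_shape <- function(x, ...) {
  cat(sprintf(
    "<alpha_shape: alpha = %g m, %d kept tetrahedra, %d boundary faces, %d vertices>\n",
    x$alpha, x$n_tetrahedra_kept, x$n_boundary_faces, nrow(x$vertices)))
  invisible(x)
}
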