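#' Construct a tree point cloud
#'
#' A `point_cloud` is the raw input of every pipeline stage: an identifier
#' plus an n x 3 matrix of coordinates.  All coordinates are in metres;
#' no unit detection is attempted.
#'
#' @param points numeric matrix (or coercible) with three columns x, y, z
#'   in metres.  Rows with non-finite coordinates are rejected.
#' @param tree_id character identifier for the tree.
#' @return An object of class `point_cloud`: a list with elements
#'   `tree_id`, `points` (n x 3 matrix with columns x, y, z) and `n`.
#' @examples
#' pc <- point_cloud(matrix(runif(30), ncol = 3), tree_id = "demo")
#' pc
#' @export
point_cloud <- function(points, tree_id = "tree") {
  pts <- as.matrix(points)
  if (is.null(dim(pts)) || ncol(pts) != 3)
    stop("'points' must have three columns (x, y, z)")
  storage.mode(pts) <- "double"
  if (nrow(pts) < 1) stop("point cloud is empty")
  if (!all(is.finite(pts))) stop("point cloud contains non-finite coordinates")
  colnames(pts) <- c("x", "y", "z")
  rownames(pts) <- NULL
  structure(list(tree_id = as.character(tree_id)[1], points = pts,
                 n = nrow(pts)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  rng <- apply(x$points, 2, range)
  cat(sprintf("<point_cloud '%s': %d points>\n", x$tree_id, x$n))
  cat(sprintf("  x: [%.3f, %.3f] m  y: [%.3f, %.3f] m  z: [%.3f, %.3f] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

# Accept a point_cloud or bare matrix; return the coordinate matrix.
as_xyz <- function(x) {
  if (inherits(x, "point_cloud")) return(x$points)
  pts <- as.matrix(x)
  if (ncol(pts) != 3) stop("expected a point_cloud or an n x 3 matrix")
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y", "z")
  pts
}

cloud_id <- function(x, default = "cloud") {
  if (inherits(x, "point_cloud")) x$tree_id else default
}

# Apply a function to the coordinates, keeping the identity.
transform_cloud <- function(x, f) {
  point_cloud(f(as_xyz(x)), tree_id = cloud_id(x))
}
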