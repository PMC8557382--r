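#' Two-way nearest-neighbour selection between two point sets
#'
#' For each point of B, its nearest neighbour in A is found (and vice
#' versa); `a_near` collects the points of A that are the nearest
#' neighbour of at least one point of B, and symmetrically for `b_near`.
#' The result demarcates the parts of two crowns that face each other.
#' With `max_dist` set, neighbour pairs farther apart than `max_dist`
#' are discarded before collecting.
#'
#' @param a,b [point_cloud()]s or n x 3 matrices.
#' @param max_dist optional distance cutoff in metres (`NULL` = none).
#' @return A list of class `nn_selection` with `a_near`, `b_near`
#'   (coordinate matrices), and the corresponding row indices `a_idx`,
#'   `b_idx` into the inputs.
#' @export
two_way_nn <- function(a, b, max_dist = NULL) {
  pa <- as_xyz(a)
  pb <- as_xyz(b)
  # nearest neighbour in A of every point of B, and vice versa
  nn_a <- RANN::nn2(pa, pb, k = 1)
  nn_b <- RANN::nn2(pb, pa, k = 1)
  ia <- nn_a$nn.idx[, 1]
  ib <- nn_b$nn.idx[, 1]
  if (!is.null(max_dist)) {
    if (max_dist <= 0) stop("max_dist must be positive (or NULL)")
    ia <- ia[nn_a$nn.dists[, 1] <= max_dist]
    ib <- ib[nn_b$nn.dists[, 1] <= max_dist]
  }
  a_idx <- sort(unique(ia))
  b_idx <- sort(unique(ib))
  if (length(a_idx) == 0 || length(b_idx) == 0)
    stop("no interaction: the nearest-neighbour selection is empty",
         if (!is.null(max_dist)) sprintf(" at max_dist = %g m", max_dist))
  structure(list(a_near = pa[a_idx, , drop = FALSE],
                 b_near = pb[b_idx, , drop = FALSE],
                 a_idx = a_idx, b_idx = b_idx),
            class = "nn_selection")
}

#' Oriented bounding box around the interaction zone
#'
#' The box's first axis is the horizontal unit vector from the xy
#' centroid of crown A to that of crown B; the second axis is the
#' horizontal perpendicular and the third is vertical.  Extents fit the
#' near set (`a_near` and `b_near` together) tightly in this frame; the
#' vertical extent is exactly the near set's z range, and `padding`
#' widens the two horizontal extents only.
#'
#' @param a,b the two full crown [point_cloud()]s (their xy centroids
#'   define the box orientation).
#' @param near an [two_way_nn()] selection, or a list with elements
#'   `a_near`, `b_near`.
#' @param padding extra half-width in metres added to both horizontal
#'   extents.  Default 0.
#' @return An object of class `interaction_region`: list with
#'   `box_center` (xyz), `box_axes` (3 x 3, rows are unit axes),
#'   `box_extents` (half-lengths), plus the near sets.
#' @export
oriented_box <- function(a, b, near, padding = 0) {
  pa <- as_xyz(a)
  pb <- as_xyz(b)
  if (padding < 0) stop("padding must be non-negative")
  ca <- colMeans(pa)[1:2]
  cb <- colMeans(pb)[1:2]
  d <- cb - ca
  len <- sqrt(sum(d^2))
  if (len < 1e-9)
    stop("coincident horizontal centroids: box orientation undefined")
  ax1 <- c(d / len, 0)
  ax2 <- c(-ax1[2], ax1[1], 0)
  ax3 <- c(0, 0, 1)
  axes <- rbind(ax1, ax2, ax3)
  dimnames(axes) <- NULL
  np <- rbind(near$a_near, near$b_near)
  if (is.null(np) || nrow(np) == 0) stop("near set is empty")
  proj <- np %*% t(axes)
  lo <- apply(proj, 2, min)
  hi <- apply(proj, 2, max)
  center_frame <- (lo + hi) / 2
  extents <- (hi - lo) / 2 + c(padding, padding, 0)
  structure(list(box_center = as.numeric(center_frame %*% axes),
                 box_axes = axes,
                 box_extents = as.numeric(extents),
                 a_near = near$a_near, b_near = near$b_near),
            class = "interaction_region")
}

#' @export
print.interaction_region <- function(x, ...) {
  cat(sprintf(
    "<interaction_region: %d + %d near points, extents %.2f x %.2f x %.2f m>\n",
    nrow(x$a_near), nrow(x$b_near),
    2 * x$box_extents[1], 2 * x$box_extents[2], 2 * x$box_extents[3]))
  invisible(x)
}

# rank of the centered coordinate matrix; 3 = genuinely 3-D point set
points_rank <- function(pts, tol = 1e-9) {
  if (nrow(pts) < 2) return(0L)
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv[1], 1))
}

#' Clip two crowns to an interaction region
#'
#' Keeps the points of each crown whose coordinates in the box frame lie
#' within center plus/minus extent on all three axes (closed intervals:
#' a point exactly on a box face is kept).
#'
#' @param region an [oriented_box()] result.
#' @param a,b the two crown [point_cloud()]s.
#' @return The `interaction_region` with clipped clouds added as
#'   `a_clip` and `b_clip` ([point_cloud()]s).
#' @export
clip_to_region <- function(region, a, b) {
  if (!inherits(region, "interaction_region"))
    stop("'region' must be an interaction_region")
  keep_in_box <- function(pts) {
    local <- sweep(pts %*% t(region$box_axes), 2,
                   as.numeric(region$box_center %*% t(region$box_axes)))
    abs(local[, 1]) <= region$box_extents[1] + 1e-12 &
      abs(local[, 2]) <= region$box_extents[2] + 1e-12 &
      abs(local[, 3]) <= region$box_extents[3] + 1e-12
  }
  pa <- as_xyz(a)
  pb <- as_xyz(b)
  ka <- keep_in_box(pa)
  kb <- keep_in_box(pb)
  check <- function(pts, keep, which) {
    kept <- pts[keep, , drop = FALSE]
    if (nrow(kept) < 4 || points_rank(kept) < 3)
      stop(sprintf(
        "insufficient points for surface on crown %s (%d kept, need >= 4 non-coplanar)",
        which, nrow(kept)))
    kept
  }
  region$a_clip <- point_cloud(check(pa, ka, "A"),
                               tree_id = paste0(cloud_id(a, "A"), "/clip"))
  region$b_clip <- point_cloud(check(pb, kb, "B"),
                               tree_id = paste0(cloud_id(b, "B"), "/clip"))
  region
}

#' Extract the interaction zone of two crowns
#'
#' Convenience composition of [two_way_nn()], [oriented_box()] and
#' [clip_to_region()].
#'
#' @inheritParams two_way_nn
#' @inheritParams oriented_box
#' @return An `interaction_region` with `a_clip` and `b_clip` filled.
#' @export
interaction_zone <- function(a, b, max_dist = NULL, padding = 0) {
  near <- two_way_nn(a, b, max_dist = max_dist)
  region <- oriented_box(a, b, near, padding = padding)
  clip_to_region(region, a, b)
}
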