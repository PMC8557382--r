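#' Voxelize a point cloud
#'
#' Partitions space into cubes of edge `voxel_size` anchored at the
#' cloud's minimum corner and counts points per occupied voxel.  Used to
#' summarize point density; the crown-base profile itself is computed on
#' points (see [height_histogram()]).
#'
#' @param cloud a [point_cloud()] or n x 3 matrix.
#' @param voxel_size voxel edge length in metres.
#' @return A data frame of class `voxel_grid` with integer voxel indices
#'   `ix`, `iy`, `iz` (0-based) and `count`, plus attributes `origin` and
#'   `voxel_size`.  `sum(count)` equals the number of points.
#' @export
voxelize <- function(cloud, voxel_size) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a positive number")
  pts <- as_xyz(cloud)
  origin <- apply(pts, 2, min)
  idx <- floor(sweep(pts, 2, origin) / voxel_size)
  storage.mode(idx) <- "integer"
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  tab <- table(key)
  first <- !duplicated(key)
  ord <- match(names(tab), key[first])
  uf <- idx[first, , drop = FALSE]
  out <- data.frame(ix = uf[ord, 1], iy = uf[ord, 2], iz = uf[ord, 3],
                    count = as.integer(tab))
  out <- out[order(out$iz, out$iy, out$ix), ]
  rownames(out) <- NULL
  structure(out, origin = origin, voxel_size = voxel_size,
            class = c("voxel_grid", "data.frame"))
}

#' Vertical point-count histogram of a cloud
#'
#' The vertical density profile used to locate the crown base: bins of
#' width `bin_width` spanning the cloud's z range, with per-bin counts
#' and fractions of the total point count.  A cloud with all z equal
#' yields a single bin with fraction 1.
#'
#' @param cloud a [point_cloud()] or n x 3 matrix.
#' @param bin_width bin width in metres.
#' @return An object of class `height_histogram`: list with `bin_edges`
#'   (length nbins + 1), `counts`, `fractions`, `bin_width`.
#' @export
height_histogram <- function(cloud, bin_width) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0)
    stop("bin_width must be a positive number")
  z <- as_xyz(cloud)[, 3]
  zmin <- min(z)
  zmax <- max(z)
  nb <- max(1L, as.integer(ceiling((zmax - zmin) / bin_width - 1e-9)))
  idx <- pmin(floor((z - zmin) / bin_width), nb - 1L) + 1L
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_edges = zmin + bin_width * (0:nb),
                 counts = counts,
                 fractions = counts / length(z),
                 bin_width = bin_width),
            class = "height_histogram")
}

#' @export
print.height_histogram <- function(x, ...) {
  cat(sprintf("<height_histogram: %d bins of %.3g m over [%.2f, %.2f] m>\n",
              length(x$counts), x$bin_width,
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

#' Plot the vertical density profile
#'
#' Horizontal bar profile of per-bin point fractions against height,
#' with the detection threshold drawn as a vertical line, so the
#' crown-base decision can be inspected visually.
#'
#' @param x a [height_histogram()].
#' @param threshold density threshold to mark (fraction of points).
#' @param ... passed to [graphics::plot()].
#' @export
plot.height_histogram <- function(x, threshold = 0.015, ...) {
  mids <- x$bin_edges[-length(x$bin_edges)] + x$bin_width / 2
  graphics::plot(x$fractions, mids, type = "s", xlab = "fraction of points",
                 ylab = "height (m)", ...)
  graphics::abline(v = threshold, col = "orange", lwd = 2)
  invisible(x)
}

#' Detect the crown base from a vertical profile
#'
#' The crown base is the lower edge of the lowest histogram bin whose
#' point fraction is strictly greater than `threshold`.  Ties at exactly
#' the threshold do not trigger detection.
#'
#' @param hist a [height_histogram()].
#' @param threshold density threshold as a fraction of total points,
#'   in (0, 1).  Default 0.015.
#' @return crown base height in metres.
#' @export
detect_crown_base <- function(hist, threshold = 0.015) {
  if (!inherits(hist, "height_histogram"))
    stop("'hist' must be a height_histogram")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  hit <- which(hist$fractions > threshold)
  if (length(hit) == 0)
    stop(sprintf(
      "no crown detected: no bin fraction exceeds %g (max observed %g)",
      threshold, max(hist$fractions)))
  hist$bin_edges[hit[1]]
}

#' Separate crown from bole
#'
#' Builds the vertical point-density profile with bins equal to the
#' voxel edge length, finds the crown base with [detect_crown_base()],
#' and splits the cloud: points with z greater than or equal to the
#' base height are crown, the rest bole.  The partition is exhaustive
#' and exclusive.
#'
#' @param cloud a [point_cloud()].
#' @param voxel_size resolution in metres; also the histogram bin width.
#'   Default 0.05 m.
#' @param threshold density threshold as a fraction of total points.
#'   Default 0.015.
#' @return An object of class `crown_segmentation`: list with
#'   `crown_base_height`, `crown` and `bole` ([point_cloud()]s; `bole`
#'   is `NULL` when empty), `histogram`, `threshold_used`,
#'   `voxel_size_used`.
#' @export
segment_crown <- function(cloud, voxel_size = 0.05, threshold = 0.015) {
  pts <- as_xyz(cloud)
  id <- cloud_id(cloud)
  hist <- height_histogram(pts, bin_width = voxel_size)
  base <- detect_crown_base(hist, threshold = threshold)
  in_crown <- pts[, 3] >= base
  if (!any(in_crown)) stop("no crown detected: crown subset empty")
  crown <- point_cloud(pts[in_crown, , drop = FALSE],
                       tree_id = paste0(id, "/crown"))
  bole <- if (any(!in_crown))
    point_cloud(pts[!in_crown, , drop = FALSE],
                tree_id = paste0(id, "/bole"))
  else NULL
  structure(list(crown_base_height = base, crown = crown, bole = bole,
                 histogram = hist, threshold_used = threshold,
                 voxel_size_used = voxel_size),
            class = "crown_segmentation")
}

#' @export
print.crown_segmentation <- function(x, ...) {
  cat(sprintf(
    "<crown_segmentation: base %.3f m, %d crown / %d bole points (P = %g)>\n",
    x$crown_base_height, x$crown$n,
    if (is.null(x$bole)) 0L else x$bole$n, x$threshold_used))
  invisible(x)
}
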