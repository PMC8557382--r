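#' Match facing triangles of two surfaces
#'
#' Two-way nearest-neighbour search on face centroids, mirroring the
#' point-level search of [two_way_nn()]: a face of U enters `uv_pairs`
#' when it is the nearest centroid of at least one face of V, and it is
#' paired with its own nearest centroid on V (symmetrically for
#' `vu_pairs`).  This selects the triangles on the facing sides of the
#' two surfaces and discards interior/back-side faces.
#'
#' @param u,v [triangle_mesh()]es.
#' @param max_dist optional centroid-distance cutoff in metres; matched
#'   pairs farther apart are excluded from both selection and averaging.
#' @return A list of class `matched_face_pairs` with `uv_pairs` and
#'   `vu_pairs` (two-column index matrices plus a `dist` attribute
#'   column), and counts `j = nrow(uv_pairs)`, `k = nrow(vu_pairs)`.
#' @export
match_faces <- function(u, v, max_dist = NULL) {
  if (!inherits(u, "triangle_mesh") || !inherits(v, "triangle_mesh"))
    stop("'u' and 'v' must be triangle_mesh objects")
  cu <- u$face_centroids
  cv <- v$face_centroids
  nn_uv <- RANN::nn2(cv, cu, k = 1)  # for each U face: nearest V face
  nn_vu <- RANN::nn2(cu, cv, k = 1)  # for each V face: nearest U face
  sel_u <- unique(nn_vu$nn.idx[, 1])
  sel_v <- unique(nn_uv$nn.idx[, 1])
  if (!is.null(max_dist)) {
    if (max_dist <= 0) stop("max_dist must be positive (or NULL)")
    sel_u <- unique(nn_vu$nn.idx[nn_vu$nn.dists[, 1] <= max_dist, 1])
    sel_v <- unique(nn_uv$nn.idx[nn_uv$nn.dists[, 1] <= max_dist, 1])
  }
  sel_u <- sort(sel_u)
  sel_v <- sort(sel_v)
  uv <- cbind(u_face = sel_u, v_face = nn_uv$nn.idx[sel_u, 1],
              dist = nn_uv$nn.dists[sel_u, 1])
  vu <- cbind(v_face = sel_v, u_face = nn_vu$nn.idx[sel_v, 1],
              dist = nn_vu$nn.dists[sel_v, 1])
  if (!is.null(max_dist)) {
    uv <- uv[uv[, "dist"] <= max_dist, , drop = FALSE]
    vu <- vu[vu[, "dist"] <= max_dist, , drop = FALSE]
  }
  if (nrow(uv) == 0 || nrow(vu) == 0)
    stop("no facing surface: face matching selected nothing",
         if (!is.null(max_dist)) sprintf(" at max_dist = %g m", max_dist))
  structure(list(uv_pairs = uv, vu_pairs = vu,
                 j = nrow(uv), k = nrow(vu)),
            class = "matched_face_pairs")
}

#' Surface complementarity score of two matched surfaces
#'
#' For every matched pair, the sample is the dot product of the outward
#' unit normal on one surface with the inward-directed unit normal
#' (the negated outward normal) at the nearest face of the other.  Sc
#' is the average of the two directional arithmetic means and lies in
#' \[-1, 1\]: +1 when the surfaces mate perfectly (outward normals
#' anti-parallel across the gap), negative when they interpenetrate.
#'
#' @param u,v [triangle_mesh()]es with outward-oriented unit normals.
#' @param pairs a [match_faces()] result; computed if omitted.
#' @param max_dist passed to [match_faces()] when `pairs` is omitted.
#' @return An object of class `sc_result`: list with `sc`, `mean_uv`,
#'   `mean_vu`, `j`, `k`, `alpha`.
#' @export
sc_score <- function(u, v, pairs = NULL, max_dist = NULL) {
  if (is.null(pairs)) pairs <- match_faces(u, v, max_dist = max_dist)
  bad_norm <- function(m)
    any(abs(sqrt(rowSums(m$face_normals^2)) - 1) > 1e-6)
  if (bad_norm(u) || bad_norm(v))
    stop("face normals are not unit vectors")
  s_uv <- rowSums(u$face_normals[pairs$uv_pairs[, 1], , drop = FALSE] *
                  -v$face_normals[pairs$uv_pairs[, 2], , drop = FALSE])
  s_vu <- rowSums(v$face_normals[pairs$vu_pairs[, 1], , drop = FALSE] *
                  -u$face_normals[pairs$vu_pairs[, 2], , drop = FALSE])
  mean_uv <- mean(s_uv)
  mean_vu <- mean(s_vu)
  structure(list(sc = (mean_uv + mean_vu) / 2,
                 mean_uv = mean_uv, mean_vu = mean_vu,
                 j = pairs$j, k = pairs$k,
                 alpha = if (is.finite(u$alpha) || is.infinite(u$alpha))
                   u$alpha else NA_real_),
            class = "sc_result")
}

#' @export
print.sc_result <- function(x, ...) {
  cat(sprintf("<sc_result: Sc = %.4f (U->V %.4f over j = %d, V->U %.4f over k = %d)%s>\n",
              x$sc, x$mean_uv, x$j, x$mean_vu, x$k,
              if (!is.null(x$alpha) && !is.na(x$alpha))
                sprintf(", alpha = %g m", x$alpha) else ""))
  invisible(x)
}

#' Crown surface complementarity of a pair of trees
#'
#' End-to-end pipeline for one pair: segment each crown from its bole
#' ([segment_crown()]), extract the interaction zone
#' ([interaction_zone()]), build both alpha-shape surfaces
#' ([alpha_shape()]), match facing faces and score ([sc_score()]).
#' Stage errors propagate with the stage name prefixed.
#'
#' @param a,b single-tree [point_cloud()]s.
#' @param voxel_size segmentation resolution in metres (also the
#'   vertical histogram bin width).  Default 0.05 m.
#' @param threshold crown-base density threshold (fraction of points).
#'   Default 0.015.
#' @param alpha alpha-shape probe radius in metres.  Default 1 m.
#' @param max_dist optional cutoff for both two-way searches (metres).
#' @param padding horizontal padding of the interaction box (metres).
#' @return An `sc_result` additionally carrying `voxel_size`,
#'   `threshold`, `max_dist`, `padding` and the two tree ids.
#' @examples
#' \donttest{
#' pair <- make_pair(gap = 0.4, seed = 21)
#' pair_sc(pair$a, pair$b)
#' }
#' @export
pair_sc <- function(a, b, voxel_size = 0.05, threshold = 0.015,
                    alpha = 1, max_dist = NULL, padding = 0) {
  seg_a <- stage("segment_crown(A)",
                 segment_crown(a, voxel_size = voxel_size,
                               threshold = threshold))
  seg_b <- stage("segment_crown(B)",
                 segment_crown(b, voxel_size = voxel_size,
                               threshold = threshold))
  zone <- stage("interaction_zone",
                interaction_zone(seg_a$crown, seg_b$crown,
                                 max_dist = max_dist, padding = padding))
  mesh_a <- stage("alpha_shape(A)", alpha_shape(zone$a_clip, alpha = alpha))
  mesh_b <- stage("alpha_shape(B)", alpha_shape(zone$b_clip, alpha = alpha))
  pairs <- stage("match_faces", match_faces(mesh_a, mesh_b,
                                            max_dist = max_dist))
  res <- stage("sc_score", sc_score(mesh_a, mesh_b, pairs))
  res$alpha <- alpha
  res$voxel_size <- voxel_size
  res$threshold <- threshold
  res$max_dist <- max_dist
  res$padding <- padding
  res$tree_ids <- c(cloud_id(a, "A"), cloud_id(b, "B"))
  res
}

#' Sensitivity of Sc to the alpha value
#'
#' Recomputes the surface and score stages over a grid of alpha values;
#' segmentation and interaction-zone extraction are computed once.  An
#' alpha that yields an empty alpha shape (or no facing faces) is
#' recorded as a missing row rather than failing the sweep.
#'
#' @inheritParams pair_sc
#' @param alphas strictly increasing vector of alpha values in metres.
#'   Default `c(0.2, 0.4, 0.6, 1, 2, 3, 5, 10)`.
#' @return A data frame of class `alpha_sweep` with columns `alpha`,
#'   `sc`, `mean_uv`, `mean_vu`, `j`, `k`, `ok`, `note`.
#' @export
alpha_sweep <- function(a, b, alphas = c(0.2, 0.4, 0.6, 1, 2, 3, 5, 10),
                        voxel_size = 0.05, threshold = 0.015,
                        max_dist = NULL, padding = 0) {
  if (length(alphas) < 1 || any(alphas <= 0) ||
      (length(alphas) > 1 && any(diff(alphas) <= 0)))
    stop("alphas must be strictly increasing and positive")
  seg_a <- stage("segment_crown(A)",
                 segment_crown(a, voxel_size = voxel_size,
                               threshold = threshold))
  seg_b <- stage("segment_crown(B)",
                 segment_crown(b, voxel_size = voxel_size,
                               threshold = threshold))
  zone <- stage("interaction_zone",
                interaction_zone(seg_a$crown, seg_b$crown,
                                 max_dist = max_dist, padding = padding))
  rows <- lapply(alphas, function(al) {
    res <- tryCatch({
      mesh_a <- alpha_shape(zone$a_clip, alpha = al)
      mesh_b <- alpha_shape(zone$b_clip, alpha = al)
      sc_score(mesh_a, mesh_b, match_faces(mesh_a, mesh_b,
                                           max_dist = max_dist))
    }, error = function(e) e)
    if (inherits(res, "error"))
      data.frame(alpha = al, sc = NA_real_, mean_uv = NA_real_,
                 mean_vu = NA_real_, j = NA_integer_, k = NA_integer_,
                 ok = FALSE, note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    else
      data.frame(alpha = al, sc = res$sc, mean_uv = res$mean_uv,
                 mean_vu = res$mean_vu, j = res$j, k = res$k,
                 ok = TRUE, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("alpha_sweep", "data.frame")
  out
}

#' Summarize alpha sweeps across many pairs
#'
#' @param sweeps a list of [alpha_sweep()] data frames (one per pair),
#'   or one long data frame with a `pair_id` column.
#' @return A data frame with per-alpha `mean_sc`, `median_sc`,
#'   `n_pairs` (rows entering the summary) and `n_missing`.
#' @export
sweep_summary <- function(sweeps) {
  long <- if (is.data.frame(sweeps)) sweeps else do.call(rbind, sweeps)
  if (nrow(long) == 0) stop("no sweep rows")
  out <- do.call(rbind, lapply(split(long, long$alpha), function(g) {
    ok <- is.finite(g$sc)
    data.frame(alpha = g$alpha[1],
               mean_sc = if (any(ok)) mean(g$sc[ok]) else NA_real_,
               median_sc = if (any(ok)) median(g$sc[ok]) else NA_real_,
               n_pairs = sum(ok), n_missing = sum(!ok))
  }))
  out <- out[order(out$alpha), ]
  rownames(out) <- NULL
  out
}
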