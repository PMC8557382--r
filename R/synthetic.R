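#' Simulate a single tree point cloud with known ground truth
#'
#' The synthetic tree emulates a TLS-scanned individual: a sparsely
#' sampled cylindrical bole from the ground to `stem_height`, and a
#' crown modelled as an ellipsoidal shell sitting on top of the bole
#' (the crown base equals `stem_height` by construction), with Gaussian
#' radial noise on the shell, a fraction of interior points emulating
#' inner-branch returns, and optional straight outward "branch spurs"
#' that give the surface the convex/concave relief real crowns have.
#' Shell sampling is weighted toward the lower hemisphere (linearly in
#' the polar cosine), emulating the occlusion bias of a ground-based
#' scanner that sees the crown underside far better than its top; this
#' also gives the crown base the sharp density onset that the
#' vertical-profile segmentation relies on in real scans.
#'
#' @param stem_height bole height in metres; also the true crown base.
#' @param crown_radius length-3 ellipsoid semi-axes (x, y, z) in metres.
#' @param crown_points total crown points (shell + interior).
#' @param stem_points bole points.
#' @param surface_noise_sd Gaussian noise sd along the shell normal (m).
#' @param interior_fraction fraction of `crown_points` placed uniformly
#'   inside the ellipsoid.  Default 0.1.
#' @param n_spurs number of branch spurs; `spur_length` their length in
#'   metres beyond the shell; `spur_points` points per spur.
#' @param stem_radius bole cylinder radius in metres.
#' @param position xy position of the stem axis in metres.
#' @param tree_id identifier for the generated cloud.
#' @param seed RNG seed; the same seed reproduces the same cloud.
#' @return A list with `cloud` (a [point_cloud()]) and `truth` (list
#'   with `crown_base_height`, `crown_center`, `crown_radius`).
#' @export
make_tree <- function(stem_height = 12, crown_radius = c(3, 3, 1.2),
                      crown_points = 12000, stem_points = 800,
                      surface_noise_sd = 0.02, interior_fraction = 0.1,
                      n_spurs = 20, spur_length = 0.4, spur_points = 12,
                      stem_radius = 0.15, position = c(0, 0),
                      tree_id = "sim_tree", seed = 1) {
  stopifnot(length(crown_radius) == 3, all(crown_radius > 0),
            crown_points >= 0, stem_points >= 0, surface_noise_sd >= 0,
            interior_fraction >= 0, interior_fraction <= 1)
  center <- c(position[1], position[2], stem_height + crown_radius[3])
  pts <- with_seed(seed, {
    n_int <- round(interior_fraction * crown_points)
    n_shell <- crown_points - n_int
    blocks <- list()
    if (n_shell > 0) {
      dir <- unit_sphere(n_shell, underside = TRUE)
      p0 <- sweep(sweep(dir, 2, crown_radius, "*"), 2, center, "+")
      if (surface_noise_sd > 0) {
        nrm <- sweep(dir, 2, crown_radius, "/")  # ellipsoid surface normal
        nrm <- nrm / sqrt(rowSums(nrm^2))
        p0 <- p0 + nrm * rnorm(n_shell, 0, surface_noise_sd)
      }
      blocks$shell <- p0
    }
    if (n_int > 0) {
      dir <- unit_sphere(n_int) * runif(n_int)^(1 / 3)
      blocks$interior <- sweep(sweep(dir, 2, crown_radius, "*"), 2,
                               center, "+")
    }
    if (n_spurs > 0 && spur_points > 0 && spur_length > 0) {
      anchor <- unit_sphere(n_spurs)
      out <- sweep(anchor, 2, crown_radius, "/")
      out <- out / sqrt(rowSums(out^2))
      base_pt <- sweep(sweep(anchor, 2, crown_radius, "*"), 2, center, "+")
      idx <- rep(seq_len(n_spurs), each = spur_points)
      t_ <- runif(n_spurs * spur_points, 0, spur_length)
      sp <- base_pt[idx, , drop = FALSE] + out[idx, , drop = FALSE] * t_
      if (surface_noise_sd > 0)
        sp <- sp + matrix(rnorm(length(sp), 0, surface_noise_sd),
                          ncol = 3)
      blocks$spurs <- sp
    }
    if (stem_points > 0) {
      th <- runif(stem_points, 0, 2 * pi)
      r <- stem_radius + if (surface_noise_sd > 0)
        rnorm(stem_points, 0, surface_noise_sd) else 0
      blocks$stem <- cbind(position[1] + r * cos(th),
                           position[2] + r * sin(th),
                           runif(stem_points, 0, stem_height))
    }
    do.call(rbind, blocks)
  })
  if (is.null(pts) || nrow(pts) == 0) stop("zero points generated")
  list(cloud = point_cloud(pts, tree_id = tree_id),
       truth = list(crown_base_height = stem_height,
                    crown_center = center, crown_radius = crown_radius))
}

# Random directions on the unit sphere.  With underside = TRUE the polar
# cosine u gets density (1 - u)/2: twice the uniform density at the
# bottom pole, tapering to zero at the top (ground-scanner occlusion).
unit_sphere <- function(n, underside = FALSE) {
  u <- if (underside) 1 - 2 * sqrt(runif(n)) else runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - u^2, 0))
  cbind(s * cos(phi), s * sin(phi), u)
}

#' Simulate a pair of neighbouring trees
#'
#' Two synthetic trees ([make_tree()]) placed along the x axis so that
#' the horizontal clearance between their nominal crown envelopes along
#' the inter-centroid line equals `gap` (metres): positive gap models
#' crown shyness (a channel between the crowns), negative gap makes the
#' envelopes interpenetrate by `|gap|` (overlapping crowns).  The gap is
#' measured between noise-free envelopes; shell noise and spurs can
#' bridge small positive gaps, as touching twigs do.
#'
#' @param gap clearance (+) or interpenetration depth (-) in metres.
#' @param seed master seed; both trees derive their own seeds from it.
#' @param crown_radius,crown_radius_b semi-axes of the two crowns
#'   (B defaults to A's).
#' @param ... further arguments passed to [make_tree()] for both trees.
#' @return A list with `a`, `b` ([point_cloud()]s) and `truth` (list
#'   with `gap`, `overlap = gap < 0`, `centroid_distance`,
#'   `crown_base_height`).
#' @export
make_pair <- function(gap = 0.5, seed = 1, crown_radius = c(3, 3, 1.2),
                      crown_radius_b = crown_radius, ...) {
  rxa <- crown_radius[1]
  rxb <- crown_radius_b[1]
  if (abs(gap) >= rxa + rxb)
    stop(sprintf("|gap| = %g m exceeds the summed crown radii (%g m)",
                 abs(gap), rxa + rxb))
  d <- rxa + rxb + gap
  base_seed <- abs(seed) %% 1000000000
  ta <- make_tree(crown_radius = crown_radius, position = c(0, 0),
                  tree_id = "sim_a", seed = base_seed, ...)
  tb <- make_tree(crown_radius = crown_radius_b, position = c(d, 0),
                  tree_id = "sim_b", seed = base_seed + 715827881, ...)
  list(a = ta$cloud, b = tb$cloud,
       truth = list(gap = gap, overlap = gap < 0,
                    centroid_distance = d,
                    crown_base_height = c(a = ta$truth$crown_base_height,
                                          b = tb$truth$crown_base_height)))
}

#' Simulate a cohort of tree pairs
#'
#' Generates `n_pairs` pairs, alternating non-overlapping (positive
#' gap) and overlapping (negative gap) labels so the two groups are as
#' balanced as the count allows, with gaps drawn uniformly from the
#' per-label ranges and per-pair seeds derived from the master seed.
#'
#' @param n_pairs number of pairs (>= 2).
#' @param seed master seed; fixes gaps and every per-pair cloud.
#' @param gap_nonoverlap,gap_overlap gap ranges (metres) for the two
#'   labels.
#' @param ... passed to [make_pair()] (and on to [make_tree()]).
#' @return A list of class `crown_cohort` with `pairs` (list of
#'   [make_pair()] results) and `truth` (data frame with `pair_id`,
#'   `tree_1`, `tree_2`, `gap_m`, `overlap`, `crown_base_m`, `seed`).
#' @export
make_cohort <- function(n_pairs = 14, seed = 1,
                        gap_nonoverlap = c(0.15, 0.9),
                        gap_overlap = c(-2, -0.3), ...) {
  if (n_pairs < 2) stop("n_pairs must be at least 2")
  overlap <- rep(c(FALSE, TRUE), length.out = n_pairs)
  gaps <- with_seed(abs(seed) %% 1000000000, {
    ifelse(overlap,
           runif(n_pairs, gap_overlap[1], gap_overlap[2]),
           runif(n_pairs, gap_nonoverlap[1], gap_nonoverlap[2]))
  })
  pseed <- (abs(seed) %% 1000000) * 1000 + seq_len(n_pairs)
  pairs <- vector("list", n_pairs)
  truth <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    p <- make_pair(gap = gaps[i], seed = pseed[i], ...)
    pid <- sprintf("pair_%02d", i)
    p$a$tree_id <- sprintf("%s_a", pid)
    p$b$tree_id <- sprintf("%s_b", pid)
    pairs[[i]] <- p
    truth[[i]] <- data.frame(pair_id = pid,
                             tree_1 = p$a$tree_id, tree_2 = p$b$tree_id,
                             gap_m = gaps[i], overlap = overlap[i],
                             crown_base_m = p$truth$crown_base_height[["a"]],
                             seed = pseed[i], stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs, truth = do.call(rbind, truth)),
            class = "crown_cohort")
}

#' @export
print.crown_cohort <- function(x, ...) {
  cat(sprintf("<crown_cohort: %d pairs (%d overlapping, %d non-overlapping)>\n",
              nrow(x$truth), sum(x$truth$overlap), sum(!x$truth$overlap)))
  invisible(x)
}
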