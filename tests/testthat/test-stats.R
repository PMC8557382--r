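test_that("pair slenderness is the mean of the two height/DBH ratios", {
  tm <- guyana_trees()
  row <- function(id) tm[tm$tree_id == id, ]
  expect_equal(round(pair_slenderness(row("40_10"), row("40_11")), 2), 0.76)
  expect_equal(round(pair_slenderness(row("40_12"), row("60_12")), 2), 0.66)
  t_same <- list(dbh_cm = 50, height_m = 25)
  expect_identical(pair_slenderness(t_same, t_same), 0.5)
  expect_error(pair_slenderness(list(dbh_cm = -1, height_m = 10), t_same),
               "positive")
})

test_that("every bundled pair-slenderness value reproduces from DBH and height", {
  tm <- guyana_trees()
  pr <- guyana_pairs()
  ps <- mapply(function(a, b)
    pair_slenderness(tm[tm$tree_id == a, ], tm[tm$tree_id == b, ]),
    pr$tree_1, pr$tree_2)
  expect_equal(round(unname(ps), 2), pr$pair_slenderness)
})

test_that("OLS of Sc on slenderness returns slope, R2 and slope p-value", {
  # perfectly collinear records
  rec <- data.frame(pair_slenderness = 1:10 / 10, sc = 2 * (1:10 / 10) - 0.5)
  fit <- suppressWarnings(regress_sc_on_slenderness(rec))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$adjusted_r_squared, 1)
  expect_equal(fit$slope, 2)

  # parameter recovery: sc = 1 * slenderness + noise
  rec2 <- with_seed(31, {
    x <- runif(200, 0.3, 0.9)
    data.frame(pair_slenderness = x, sc = x + rnorm(200, 0, 0.05))
  })
  fit2 <- regress_sc_on_slenderness(rec2)
  se <- summary(fit2$model)$coefficients[2, 2]
  expect_lt(abs(fit2$slope - 1), 3 * se)
  # adjusted R2 closed form
  expect_equal(fit2$adjusted_r_squared,
               1 - (1 - fit2$r_squared) * (fit2$n - 1) / (fit2$n - 2))

  expect_error(regress_sc_on_slenderness(
    data.frame(pair_slenderness = rep(0.5, 5), sc = runif(5))),
    "zero variance")
  expect_error(regress_sc_on_slenderness(
    data.frame(pair_slenderness = 1:2 / 2, sc = c(0.1, 0.2))),
    "at least 3")
})

test_that("group comparison flags separated groups and not identical ones", {
  rec <- data.frame(sc = c(0, 0, 0, 1, 1, 1),
                    overlap = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  g <- compare_overlap_groups(rec)
  expect_equal(g$mean_nonoverlap - g$mean_overlap, 1)
  expect_lt(g$p_value, 1e-6)
  expect_equal(g$n_overlap + g$n_nonoverlap, 6)

  same <- data.frame(sc = rep(c(0.3, 0.5), 2),
                     overlap = c(TRUE, TRUE, FALSE, FALSE))
  g2 <- compare_overlap_groups(same)
  expect_equal(g2$t_statistic, 0)
  expect_equal(g2$p_value, 1)

  expect_error(compare_overlap_groups(
    data.frame(sc = c(1, 2, 3), overlap = c(TRUE, FALSE, FALSE))),
    "at least 2")
})

test_that("the 7 + 7 design has power for a 0.38 mean gap at sigma 0.15", {
  hits <- with_seed(37, {
    vapply(1:200, function(i) {
      rec <- data.frame(
        sc = c(rnorm(7, 0.267, 0.15), rnorm(7, 0.647, 0.15)),
        overlap = rep(c(TRUE, FALSE), each = 7))
      compare_overlap_groups(rec)$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.8)
})

test_that("Shapiro-Wilk wrapper is calibrated and has power", {
  res <- with_seed(41, {
    norm_p <- vapply(1:100, function(i)
      normality_check(rnorm(100))$p_value, numeric(1))
    exp_p <- vapply(1:100, function(i)
      normality_check(rexp(100))$p_value, numeric(1))
    c(calib = mean(norm_p > 0.05), power = mean(exp_p < 0.05))
  })
  expect_gte(res[["calib"]], 0.9)
  expect_gte(res[["power"]], 0.9)

  w <- normality_check(c(-1, 0, 1))
  expect_gt(w$statistic, 0)
  expect_lte(w$statistic, 1)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "between 3 and 5000")
})
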