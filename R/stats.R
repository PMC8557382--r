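#' Average slenderness of a pair of trees
#'
#' Pair slenderness is the mean of the two trees' slenderness ratios,
#' each the tree height (m) divided by its DBH (cm):
#' `(H1/D1 + H2/D2) / 2`.  With these units mature tropical trees fall
#' around 0.4-0.9.
#'
#' @param t1,t2 single rows of a [tree_metrics()] data frame, or lists
#'   with elements `dbh_cm` and `height_m`.
#' @return pair slenderness (dimensionless in the m/cm convention).
#' @export
pair_slenderness <- function(t1, t2) {
  s <- function(t) {
    d <- as.numeric(t[["dbh_cm"]])
    h <- as.numeric(t[["height_m"]])
    if (!is.finite(d) || d <= 0 || !is.finite(h) || h <= 0)
      stop("dbh_cm and height_m must be positive")
    h / d
  }
  (s(t1) + s(t2)) / 2
}

#' Regress Sc on pair slenderness
#'
#' Ordinary least squares of the complementarity score on pair
#' slenderness across pairs, with the two-sided t-test on the slope.
#'
#' @param records data frame with numeric columns `sc` and
#'   `pair_slenderness` (one row per tree pair).
#' @return An object of class `sc_regression`: list with `slope`,
#'   `intercept`, `r_squared`, `adjusted_r_squared`, `p_value_slope`,
#'   `n`, and the underlying `lm` fit as `model`.
#' @export
regress_sc_on_slenderness <- function(records) {
  if (!all(c("sc", "pair_slenderness") %in% names(records)))
    stop("records need columns 'sc' and 'pair_slenderness'")
  records <- records[is.finite(records$sc) &
                     is.finite(records$pair_slenderness), , drop = FALSE]
  n <- nrow(records)
  if (n < 3) stop("need at least 3 pairs for regression")
  if (sd(records$pair_slenderness) == 0)
    stop("zero variance in pair slenderness")
  fit <- lm(sc ~ pair_slenderness, data = records)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 adjusted_r_squared = sm$adj.r.squared,
                 p_value_slope = sm$coefficients[2, 4],
                 n = n, model = fit),
            class = "sc_regression")
}

#' @export
print.sc_regression <- function(x, ...) {
  cat(sprintf(
    "<sc_regression: slope %.3f, adj R^2 = %.3f, slope p = %.4g, n = %d>\n",
    x$slope, x$adjusted_r_squared, x$p_value_slope, x$n))
  invisible(x)
}

#' Compare Sc between overlapping and non-overlapping pairs
#'
#' Independent two-sample t-test of the complementarity score between
#' the two visually assigned overlap groups (pooled variance by
#' default, Welch optionally).  Overlap labels are user-supplied: they
#' come from inspection of the crowns, never from Sc itself.
#'
#' @param records data frame with numeric `sc` and logical `overlap`.
#' @param welch use the Welch (unequal-variance) test instead of the
#'   pooled-variance test.  Default `FALSE`.
#' @return An object of class `group_comparison`: list with
#'   `mean_overlap`, `mean_nonoverlap`, `t_statistic`, `p_value`,
#'   `n_overlap`, `n_nonoverlap`, `variant`.
#' @export
compare_overlap_groups <- function(records, welch = FALSE) {
  if (!all(c("sc", "overlap") %in% names(records)))
    stop("records need columns 'sc' and 'overlap'")
  ov <- records$sc[records$overlap %in% TRUE]
  no <- records$sc[records$overlap %in% FALSE]
  if (length(ov) < 2 || length(no) < 2)
    stop("each overlap group needs at least 2 pairs")
  tt <- tryCatch(t.test(ov, no, var.equal = !welch), error = function(e) {
    if (!grepl("constant", conditionMessage(e))) stop(e)
    # both groups (essentially) constant: degenerate closed form
    if (isTRUE(all.equal(mean(ov), mean(no))))
      list(statistic = c(t = 0), p.value = 1)
    else
      list(statistic = c(t = sign(mean(ov) - mean(no)) * Inf), p.value = 0)
  })
  structure(list(mean_overlap = mean(ov), mean_nonoverlap = mean(no),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 n_overlap = length(ov), n_nonoverlap = length(no),
                 variant = if (welch) "welch" else "pooled"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison (%s t-test): mean Sc %.3f (overlap, n = %d) vs %.3f (non-overlap, n = %d), t = %.2f, p = %.4g>\n",
    x$variant, x$mean_overlap, x$n_overlap, x$mean_nonoverlap,
    x$n_nonoverlap, x$t_statistic, x$p_value))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' @param values numeric vector, 3 to 5000 finite values, not constant.
#' @return list with `statistic` (W), `p_value` and `n`.
#' @export
normality_check <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk needs between 3 and 5000 values")
  if (sd(x) == 0) stop("constant input")
  sw <- shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       n = length(x))
}
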