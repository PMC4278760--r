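# Steps 3-4: select the least-significantly activated voxel surviving the
# thresholding procedure, then test every non-significant voxel's contrast
# against it. Voxels whose contrast is not significantly smaller are "in
# limbo": they differ neither from baseline nor from activated regions.

#' Select the comparison voxel
#'
#' The significantly activated voxel with the lowest test statistic — the
#' "least significantly activated voxel". Ties are broken deterministically
#' by lexicographic (array-order) voxel index, with a warning.
#'
#' @param zmap an `il_zmap`.
#' @param clusters an `il_clusters` from [cluster_threshold()] on that map.
#' @param rule selection rule; only `"min_t_significant"` is the default
#'   documented rule. `"mean_min_cluster"` instead averages the contrast
#'   over the least-significant cluster (requires `fit` downstream support
#'   and is provided for sensitivity analyses).
#' @return an `il_comparison`: `index` (linear voxel index), `coords`
#'   (0-based array coordinates), `z`, and the selection rule.
#' @export
select_comparison_voxel <- function(zmap, clusters,
                                    rule = c("min_t_significant",
                                             "mean_min_cluster")) {
  rule <- match.arg(rule)
  sig <- which(clusters$significant & zmap$mask)
  if (!length(sig)) {
    il_abort(paste0(
      "No significantly activated voxels: if there are no significantly ",
      "activated areas, there can be no regions that are in limbo."),
      "inlimbo_error_no_significant")
  }
  zs <- zmap$z[sig]
  zmin <- min(zs)
  cand <- sig[zs == zmin]
  if (length(cand) > 1) {
    warn(sprintf(
      "%d significant voxels tie for the minimum statistic; taking the lowest array index.",
      length(cand)))
  }
  idx <- min(cand)
  structure(list(
    index = idx,
    coords = as.integer(vox_coords(idx, zmap$dim)) - 1L,
    z = zmap$z[idx],
    selection_rule = rule
  ), class = "il_comparison")
}

#' @export
print.il_comparison <- function(x, ...) {
  cat(sprintf("<il_comparison> voxel (%s), z = %.3f, rule = %s\n",
              paste(x$coords, collapse = ", "), x$z, x$selection_rule))
  invisible(x)
}

#' Single-subject in-limbo t-test for one voxel
#'
#' Tests whether the contrast in `voxel` is significantly smaller than in
#' the comparison voxel:
#' `t = (c'b_comp - c'b_voxel) / sqrt(Var_comp + Var_voxel - 2 Cov)`,
#' one-sided with the fit's degrees of freedom. The cross-voxel sandwich
#' covariance enters the pooled variance; positive covariance sharpens the
#' test.
#'
#' @param fit a sandwich `il_fit`.
#' @param comparison an `il_comparison` (or a fit column index).
#' @param voxel fit column index of the tested voxel.
#' @param alpha significance level of the one-sided test.
#' @return a list with `t`, `p` and `label` (`"less"` or `"in_limbo"`).
#' @export
limbo_test_single <- function(fit, comparison, voxel, alpha = 0.05) {
  check_sandwich(fit)
  comp_col <- comparison_column(fit, comparison)
  num <- fit$contrast[comp_col] - fit$contrast[voxel]
  pooled <- fit$variance[comp_col] + fit$variance[voxel] -
    2 * sandwich_covariance(fit, comp_col, voxel)
  if (pooled <= 0) {
    il_abort(sprintf(
      "Non-positive pooled variance for voxel pair (%d, %d): the two voxels' residual blocks are numerically identical.",
      comp_col, voxel), "inlimbo_error_degenerate")
  }
  tval <- num / sqrt(pooled)
  p <- pt(tval, fit$dof, lower.tail = FALSE)
  list(t = tval, p = p, label = if (p <= alpha) "less" else "in_limbo")
}

comparison_column <- function(fit, comparison) {
  if (inherits(comparison, "il_comparison")) {
    col <- match(comparison$index, fit$voxels)
    if (is.na(col)) {
      il_abort("Comparison voxel is not among the fitted voxels.",
               "inlimbo_error_spec")
    }
    col
  } else {
    as.integer(comparison)
  }
}

#' Group-level in-limbo test: weighted least squares over subjects
#'
#' For one voxel, `d` holds each subject's difference between the contrast
#' at that voxel and at the comparison voxel, and `sd` the corresponding
#' standard deviations `sqrt(Var_voxel + Var_comp - 2 Cov)` from each
#' subject's sandwich fit. An intercept-only WLS model with weights `1/sd`
#' (so effective precision weights `1/sd^2`) gives the group difference and
#' its variance; the residual scale is re-estimated with `n - 1` degrees of
#' freedom. The one-sided test asks whether the voxel's contrast is smaller
#' than the comparison voxel's (i.e. mean of `d` negative).
#'
#' @param d numeric vector of per-subject differences (voxel minus
#'   comparison).
#' @param sd numeric vector of per-subject standard deviations, > 0.
#' @param alpha one-sided significance level (0.05, uncorrected, is the
#'   conventional choice).
#' @return a list with `estimate` (weighted mean difference), `se`, `t`,
#'   `p`, `dof` and `label`.
#' @examples
#' limbo_test_group(d = rnorm(20, -1), sd = rep(1, 20))
#' @export
limbo_test_group <- function(d, sd, alpha = 0.05) {
  n <- length(d)
  if (n < 2) {
    il_abort("The group test needs at least 2 subjects.", "inlimbo_error_spec")
  }
  if (length(sd) != n || any(!is.finite(sd)) || any(sd <= 0)) {
    il_abort("All per-subject standard deviations must be positive.",
             "inlimbo_error_spec")
  }
  w <- 1 / sd^2
  est <- sum(w * d) / sum(w)
  rss <- sum(w * (d - est)^2)
  dof <- n - 1
  s2 <- rss / dof
  if (s2 == 0) {
    # all weighted residuals zero (e.g. constant d): no evidence scale;
    # convention: t = 0 when the estimate is 0, else sign(est) * Inf
    tval <- if (est == 0) 0 else sign(-est) * Inf
  } else {
    tval <- -est / sqrt(s2 / sum(w))
  }
  p <- pt(tval, dof, lower.tail = FALSE)
  list(estimate = est, se = if (s2 > 0) sqrt(s2 / sum(w)) else 0,
       t = tval, p = p, dof = dof,
       label = if (p <= alpha) "less" else "in_limbo")
}

#' Classify every voxel as activated, in limbo, or less activated
#'
#' Runs the in-limbo test against the comparison voxel over every analyzed
#' non-significant voxel and assembles the three-class map. With
#' `correction = "fdr"`, Benjamini-Hochberg adjusted p-values are used for
#' the less/in-limbo decision, which can only enlarge the in-limbo set; the
#' uncorrected default yields the minimum number of in-limbo voxels.
#'
#' @param zmap an `il_zmap`.
#' @param clusters an `il_clusters` for that map.
#' @param fit the sandwich `il_fit` behind the map (single-subject level).
#' @param alpha one-sided significance level of the limbo test.
#' @param correction `"none"` (default) or `"fdr"`.
#' @param comparison optionally, a pre-selected `il_comparison`.
#' @return an `il_limbo`: `labels` (factor array with levels background,
#'   less, in_limbo, activated), `t_limbo`, `p_limbo` (arrays, defined on
#'   tested voxels), `comparison`, `alpha`, `correction`.
#' @export
classify_brain <- function(zmap, clusters, fit, alpha = 0.05,
                           correction = c("none", "fdr"),
                           comparison = NULL) {
  correction <- match.arg(correction)
  check_sandwich(fit)
  comparison <- comparison %||% select_comparison_voxel(zmap, clusters)
  comp_col <- comparison_column(fit, comparison)
  covs <- sandwich_covariance_all(fit, comp_col)
  num <- fit$contrast[comp_col] - fit$contrast
  pooled <- fit$variance[comp_col] + fit$variance - 2 * covs
  test_cols <- which(!(fit$voxels %in% which(clusters$significant)) &
                       fit$voxels %in% which(zmap$mask))
  bad <- test_cols[pooled[test_cols] <= 0]
  if (length(bad)) {
    il_abort(sprintf(
      "Non-positive pooled variance for voxel pair (comparison %d, voxel %d).",
      comp_col, bad[1]), "inlimbo_error_degenerate")
  }
  tval <- num[test_cols] / sqrt(pooled[test_cols])
  p <- pt(tval, fit$dof, lower.tail = FALSE)
  p_dec <- if (correction == "fdr") p.adjust(p, "BH") else p
  assemble_limbo(zmap, clusters, test_cols_vox = fit$voxels[test_cols],
                 tval = tval, p = p, p_dec = p_dec, alpha = alpha,
                 correction = correction, comparison = comparison,
                 dof = fit$dof)
}

assemble_limbo <- function(zmap, clusters, test_cols_vox, tval, p, p_dec,
                           alpha, correction, comparison, dof) {
  dims <- zmap$dim
  lab <- array(0L, dims)                       # 0 background
  lab[clusters$significant & zmap$mask] <- 3L  # activated
  less <- p_dec <= alpha
  lab[test_cols_vox[less]] <- 1L
  lab[test_cols_vox[!less]] <- 2L
  t_arr <- array(NA_real_, dims); t_arr[test_cols_vox] <- tval
  p_arr <- array(NA_real_, dims); p_arr[test_cols_vox] <- p
  structure(list(
    labels = lab, t_limbo = t_arr, p_limbo = p_arr,
    comparison = comparison, alpha = alpha, correction = correction,
    dof = dof, mask = zmap$mask, dim = dims,
    pixdim = zmap$pixdim
  ), class = "il_limbo")
}

#' @export
print.il_limbo <- function(x, ...) {
  n <- limbo_counts(x)
  cat(sprintf(
    "<il_limbo> activated %d | in limbo %d | less %d (alpha = %g, %s)\n",
    n[["activated"]], n[["in_limbo"]], n[["less"]], x$alpha, x$correction))
  invisible(x)
}

limbo_counts <- function(x) {
  c(background = sum(x$labels == 0L & TRUE),
    less = sum(x$labels == 1L),
    in_limbo = sum(x$labels == 2L),
    activated = sum(x$labels == 3L))
}

#' Integer label codes used in exported label maps
#'
#' 0 = background (outside the analysis mask), 1 = significantly less
#' activated than the comparison voxel, 2 = in limbo, 3 = significantly
#' activated.
#'
#' @return named integer vector.
#' @export
limbo_label_codes <- function() {
  c(background = 0L, less = 1L, in_limbo = 2L, activated = 3L)
}
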