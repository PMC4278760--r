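# Group-level (level-2) pipeline: per-subject sandwich fits registered to a
# common grid, a one-sample t map across subjects converted to z, cluster
# thresholding on that map, and the WLS in-limbo test per voxel with
# precision weights from each subject's sandwich variance and covariance.

#' Level-2 z-map from per-subject contrast estimates
#'
#' One-sample t-statistic of the per-subject contrasts at each voxel,
#' converted to z with `n - 1` degrees of freedom. Voxels with zero
#' between-subject variance or missing in any subject are dropped from the
#' mask.
#'
#' @param contrasts n x V matrix of per-subject contrast estimates.
#' @param dim voxel grid dimensions (default: flat V).
#' @param voxels linear indices of columns in the grid.
#' @param mask optional logical array restricting the analysis.
#' @return an `il_zmap` with `dof = n - 1`.
#' @export
group_zmap <- function(contrasts, dim = NULL, voxels = NULL, mask = NULL) {
  C <- as.matrix(contrasts)
  n <- nrow(C)
  if (n < 2) {
    il_abort("Group analysis needs at least 2 subjects.", "inlimbo_error_spec")
  }
  dims <- dim %||% ncol(C)
  voxels <- voxels %||% seq_len(ncol(C))
  m <- colMeans(C)
  s <- sqrt(colSums(sweep(C, 2, m)^2) / (n - 1))
  ok <- s > 0 & complete.cases(t(C))
  tval <- rep(NA_real_, length(m))
  tval[ok] <- m[ok] / (s[ok] / sqrt(n))
  z <- array(NA_real_, dims)
  t_arr <- array(NA_real_, dims)
  z[voxels[ok]] <- t_to_z(tval[ok], n - 1)
  t_arr[voxels[ok]] <- tval[ok]
  msk <- array(FALSE, dims)
  msk[voxels[ok]] <- TRUE
  if (!is.null(mask)) msk <- msk & mask
  new_zmap(z, msk, n - 1L, t = t_arr)
}

#' Classify a group analysis into activated / in limbo / less
#'
#' Given per-subject sandwich fits on a common voxel grid, a level-2
#' `il_zmap` and its cluster thresholding, selects the comparison voxel on
#' the group map and runs the WLS in-limbo test ([limbo_test_group()]) over
#' every analyzed non-significant voxel. Per-subject difference standard
#' deviations combine each subject's sandwich variances at the voxel and at
#' the comparison voxel with their cross-voxel covariance.
#'
#' @param zmap level-2 `il_zmap` (from [group_zmap()]).
#' @param clusters `il_clusters` for that map.
#' @param fits list of per-subject sandwich `il_fit`s with identical voxel
#'   indexing.
#' @param alpha one-sided significance level.
#' @param correction `"none"` or `"fdr"`.
#' @param comparison optionally a pre-selected `il_comparison`.
#' @return an `il_limbo` (see [classify_brain()]).
#' @export
classify_group <- function(zmap, clusters, fits, alpha = 0.05,
                           correction = c("none", "fdr"),
                           comparison = NULL) {
  correction <- match.arg(correction)
  n <- length(fits)
  if (n < 2) {
    il_abort("Group analysis needs at least 2 subjects.", "inlimbo_error_spec")
  }
  vox <- fits[[1]]$voxels
  for (f in fits) {
    check_sandwich(f)
    if (!identical(f$voxels, vox) || !identical(f$dim, fits[[1]]$dim)) {
      il_abort("All subjects must share one voxel grid.", "inlimbo_error_spec")
    }
  }
  comparison <- comparison %||% select_comparison_voxel(zmap, clusters)
  comp_col <- match(comparison$index, vox)
  if (is.na(comp_col)) {
    il_abort("Comparison voxel is not among the fitted voxels.",
             "inlimbo_error_spec")
  }
  V <- length(vox)
  D <- matrix(NA_real_, n, V)
  S2 <- matrix(NA_real_, n, V)
  for (i in seq_len(n)) {
    f <- fits[[i]]
    covs <- sandwich_covariance_all(f, comp_col)
    D[i, ] <- f$contrast - f$contrast[comp_col]
    S2[i, ] <- f$variance + f$variance[comp_col] - 2 * covs
  }
  test_cols <- which(!(vox %in% which(clusters$significant)) &
                       vox %in% which(zmap$mask))
  ok <- colSums(S2[, test_cols, drop = FALSE] <= 0) == 0
  if (any(!ok)) {
    il_abort(sprintf(
      "Non-positive pooled variance for voxel pair (comparison %d, voxel %d).",
      comp_col, test_cols[which(!ok)[1]]), "inlimbo_error_degenerate")
  }
  Dt <- D[, test_cols, drop = FALSE]
  Wt <- 1 / S2[, test_cols, drop = FALSE]
  sw <- colSums(Wt)
  est <- colSums(Dt * Wt) / sw
  rss <- colSums(Wt * sweep(Dt, 2, est)^2)
  dof <- n - 1
  s2 <- rss / dof
  se <- sqrt(s2 / sw)
  tval <- ifelse(se > 0, -est / se, ifelse(est == 0, 0, sign(-est) * Inf))
  p <- pt(tval, dof, lower.tail = FALSE)
  p_dec <- if (correction == "fdr") p.adjust(p, "BH") else p
  assemble_limbo(zmap, clusters, test_cols_vox = vox[test_cols],
                 tval = tval, p = p, p_dec = p_dec, alpha = alpha,
                 correction = correction, comparison = comparison, dof = dof)
}
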