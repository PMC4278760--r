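#' Convert a fitted contrast into a z-map
#'
#' Per-voxel `t = c'beta / sqrt(Var)` converted to z through the probability
#' integral transform (t CDF at the fit's degrees of freedom composed with
#' the standard-normal quantile function). Voxels with zero variance
#' (constant signal) cannot be tested; they are dropped from the analysis
#' mask and their count reported.
#'
#' @param fit an `il_fit`.
#' @param dof degrees of freedom for the t-to-z transform; defaults to the
#'   fit's dof (`q - 1` for the sandwich estimator).
#' @return an `il_zmap`: list with `z` (array shaped like the voxel grid),
#'   `t`, `mask` (analyzed voxels), `dim`, `dof`, and the originating `fit`
#'   voxel indexing.
#' @export
contrast_zmap <- function(fit, dof = NULL) {
  if (!inherits(fit, "il_fit")) {
    il_abort("`fit` must be an il_fit.", "inlimbo_error_spec")
  }
  dof <- dof %||% fit$dof
  ok <- fit$variance > 0
  if (!any(ok)) {
    il_abort("All voxels have zero variance; nothing to test.",
             "inlimbo_error_degenerate")
  }
  if (any(!ok)) {
    inform(sprintf("Excluding %d zero-variance voxel(s) from the analysis mask.",
                   sum(!ok)))
  }
  dims <- fit$dim
  tval <- rep(NA_real_, prod(dims))
  tval[fit$voxels[ok]] <- fit$contrast[ok] / sqrt(fit$variance[ok])
  z <- rep(NA_real_, prod(dims))
  z[fit$voxels[ok]] <- t_to_z(tval[fit$voxels[ok]], dof)
  mask <- array(FALSE, dims)
  mask[fit$voxels[ok]] <- TRUE
  new_zmap(array(z, dims), mask, dof, t = array(tval, dims))
}

new_zmap <- function(z, mask, dof, t = NULL, pixdim = NULL, ref = NULL) {
  structure(list(z = z, t = t, mask = mask, dim = dim(z) %||% length(z),
                 dof = dof, pixdim = pixdim, ref = ref),
            class = "il_zmap")
}

#' Construct a z-map from an array of z-values
#'
#' For maps computed outside [contrast_zmap()] (e.g. a group-level map).
#'
#' @param z numeric array of z-values.
#' @param mask logical array of analyzed voxels (same shape).
#' @param dof degrees of freedom of the source t-statistics (metadata).
#' @param pixdim voxel dimensions in mm (used for volume reporting).
#' @return an `il_zmap`.
#' @export
as_zmap <- function(z, mask = NULL, dof = Inf, pixdim = NULL) {
  z <- as.array(z)
  mask <- mask %||% array(TRUE, dim(z))
  mask <- as.array(mask)
  if (!identical(dim(z), dim(mask))) {
    il_abort("`z` and `mask` must have identical shapes.", "inlimbo_error_spec")
  }
  if (any(!is.finite(z[mask]))) {
    il_abort("z must be finite inside the mask.", "inlimbo_error_spec")
  }
  new_zmap(z, mask, dof, pixdim = pixdim)
}

#' @export
print.il_zmap <- function(x, ...) {
  cat(sprintf("<il_zmap> %s voxels analyzed, dof = %s, z range [%.2f, %.2f]\n",
              sum(x$mask), format(x$dof),
              min(x$z[x$mask]), max(x$z[x$mask])))
  invisible(x)
}
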