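# broom-style accessors: every result type tidies to a voxels-as-rows
# tibble so downstream summaries compose with dplyr.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a GLM fit into a per-voxel tibble
#'
#' @param x an `il_fit`.
#' @param ... unused.
#' @return tibble with voxel index, contrast, variance, se and t.
#' @method tidy il_fit
#' @export
tidy.il_fit <- function(x, ...) {
  tibble::tibble(
    voxel = x$voxels,
    contrast = x$contrast,
    variance = x$variance,
    se = sqrt(x$variance),
    t = ifelse(x$variance > 0, x$contrast / sqrt(x$variance), NA_real_))
}

#' @method glance il_fit
#' @export
glance.il_fit <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, n_voxels = length(x$contrast),
                 dof = x$dof,
                 q = if (!is.null(x$blocks)) x$blocks$q else NA_integer_)
}

#' Tidy a z-map
#' @param x an `il_zmap`.
#' @param ... unused.
#' @return tibble with voxel coordinates (0-based), z and mask flag for
#'   analyzed voxels.
#' @method tidy il_zmap
#' @export
tidy.il_zmap <- function(x, ...) {
  idx <- which(x$mask)
  co <- vox_coords(idx, x$dim) - 1L
  colnames(co) <- c("i", "j", "k")[seq_len(ncol(co))]
  dplyr::bind_cols(tibble::as_tibble(co),
                   tibble::tibble(voxel = idx, z = x$z[idx]))
}

#' Tidy a cluster table
#' @param x an `il_clusters`.
#' @param ... unused.
#' @return the cluster tibble (one row per supra-threshold cluster).
#' @method tidy il_clusters
#' @export
tidy.il_clusters <- function(x, ...) x$clusters

#' @method glance il_clusters
#' @export
glance.il_clusters <- function(x, ...) {
  tibble::tibble(z_threshold = x$z_threshold, method = x$method,
                 alpha_cluster = x$alpha_cluster,
                 n_clusters = nrow(x$clusters),
                 n_significant_voxels = sum(x$significant))
}

#' Tidy an in-limbo classification
#' @param x an `il_limbo`.
#' @param ... unused.
#' @return tibble with voxel coordinates, label, t_limbo and p_limbo for
#'   every in-mask voxel.
#' @method tidy il_limbo
#' @export
tidy.il_limbo <- function(x, ...) {
  idx <- which(x$mask)
  co <- vox_coords(idx, x$dim) - 1L
  colnames(co) <- c("i", "j", "k")[seq_len(ncol(co))]
  lev <- names(limbo_label_codes())
  dplyr::bind_cols(
    tibble::as_tibble(co),
    tibble::tibble(voxel = idx,
                   label = factor(lev[x$labels[idx] + 1L], levels = lev),
                   t_limbo = x$t_limbo[idx],
                   p_limbo = x$p_limbo[idx]))
}

#' @method glance il_limbo
#' @export
glance.il_limbo <- function(x, ...) {
  n <- limbo_counts(x)
  tibble::tibble(n_activated = n[["activated"]], n_in_limbo = n[["in_limbo"]],
                 n_less = n[["less"]], alpha = x$alpha,
                 correction = x$correction,
                 comparison_z = x$comparison$z)
}

#' @method tidy il_run
#' @export
tidy.il_run <- function(x, ...) tidy(x$limbo)

#' @method glance il_run
#' @export
glance.il_run <- function(x, ...) glance(x$limbo)
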