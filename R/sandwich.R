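# Replication-block sandwich estimator: the run is cut into q equal-length
# "subrun" blocks, the coefficients are estimated from the across-block mean
# time course, and the contrast variance (and cross-voxel covariance) is
# estimated from the spread of per-block residuals. This is robust to both
# autocorrelation and HRF misspecification, at the price of only q - 1
# degrees of freedom.

#' Divide a run into replication blocks
#'
#' Cuts the time series and design into `q` consecutive blocks of equal
#' length `floor(T / q)`; remaining time points at the end of the run are
#' discarded. The default `q = floor(sqrt(T))` follows the square-root-of-T
#' subrun rule.
#'
#' @param y T-vector or T x V matrix of voxel time series.
#' @param design an `il_design` (or plain matrix).
#' @param q number of blocks; default `floor(sqrt(T))`.
#' @return an `il_blocks` list: `q`, `block_length`, `block_design` (list of
#'   q matrices), `block_data` (list of q data matrices), `design`, `used`
#'   (number of time points kept).
#' @examples
#' X <- as_design(cbind(x = rnorm(100), intercept = 1))
#' b <- make_blocks(rnorm(100), X)   # 10 blocks of 10
#' @export
make_blocks <- function(y, design, q = NULL) {
  Y <- as_voxel_matrix(y)
  X <- if (inherits(design, "il_design")) design else as_design(design)
  Tn <- nrow(X)
  if (nrow(Y) != Tn) {
    il_abort("Time series length does not match the design.", "inlimbo_error_spec")
  }
  if (Tn < 4L) {
    il_abort("Need at least 4 time points to form replication blocks.",
             "inlimbo_error_spec")
  }
  q <- as.integer(q %||% floor(sqrt(Tn)))
  if (q < 2L) {
    il_abort("Fewer than 2 replication blocks; the sandwich estimator needs q >= 2.",
             "inlimbo_error_spec")
  }
  L <- Tn %/% q
  if (L < 1L) {
    il_abort("More blocks than time points.", "inlimbo_error_spec")
  }
  used <- q * L
  idx <- split(seq_len(used), rep(seq_len(q), each = L))
  structure(list(
    q = q, block_length = L, used = used,
    block_design = lapply(idx, function(i) unclass(X)[i, , drop = FALSE]),
    block_data = lapply(idx, function(i) Y[i, , drop = FALSE]),
    design = X
  ), class = "il_blocks")
}

#' Sandwich GLM fit over replication blocks
#'
#' Estimates `beta` from the across-block mean time course,
#' `beta = (sum_i Xi'Xi)^-1 (sum_i Xi') ybar`, and the contrast variance with
#' the sandwich formula: bread `(sum_i Xi'Xi)^-1`, meat
#' `sum_i Xi' Sigma_hat Xi`, where `Sigma_hat` is the per-block residual
#' covariance `(q-1)^-1 sum_i r_i r_i'` (residuals `r_i = y_i - Xi beta`).
#' Per-block residuals are retained so cross-voxel covariances of the same
#' contrast can be formed later ([sandwich_covariance()]). Degrees of freedom
#' are `q - 1`: the replications are the effective sample.
#'
#' @param y T-vector, T x V matrix, or an [make_blocks()] result.
#' @param design design matrix (ignored when `y` is an `il_blocks`).
#' @param contrast contrast weights (see [contrast_spec()]).
#' @param q number of blocks (ignored when `y` is an `il_blocks`).
#' @param dim optional spatial dimensions of the voxel grid.
#' @param voxels optional linear indices of the fitted voxels in that grid.
#' @return an `il_fit` with `estimator = "sandwich"`, residual blocks
#'   retained, and `dof = q - 1`.
#' @examples
#' X <- as_design(cbind(x = rnorm(64), intercept = 1))
#' f <- fit_sandwich(matrix(rnorm(64 * 3), 64), X, c(1, 0))
#' @export
fit_sandwich <- function(y, design = NULL, contrast, q = NULL,
                         dim = NULL, voxels = NULL) {
  blocks <- if (inherits(y, "il_blocks")) y else make_blocks(y, design, q)
  q <- blocks$q; L <- blocks$block_length
  # Individual blocks may be rank deficient (e.g. a rest-only block has an
  # all-zero task column); only the pooled design must be full rank.
  X <- blocks$design
  cw <- as.numeric(contrast_spec(contrast, X))
  M <- Reduce(`+`, lapply(blocks$block_design, crossprod))      # sum Xi'Xi
  if (inherits(try(chol(M), silent = TRUE), "try-error")) {
    il_abort("Pooled block design is rank deficient.", "inlimbo_error_rank")
  }
  Minv <- chol2inv(chol(M))
  # Pooled normal equations over the kept rows: for identical block designs
  # this is exactly the mean-time-course estimator
  # (sum Xi'Xi)^-1 (sum Xi') ybar; for heterogeneous blocks it stays
  # unbiased where the shared-mean form does not.
  Sxy <- Reduce(`+`, Map(crossprod, blocks$block_design, blocks$block_data))
  beta <- Minv %*% Sxy                                          # p x V

  # residuals per block, stacked: row (i-1)*L + l is block i, time l
  E <- do.call(rbind, lapply(seq_len(q), function(i) {
    blocks$block_data[[i]] - blocks$block_design[[i]] %*% beta
  }))
  # W[i, ] = (Xi %*% Minv %*% c)': variance = sum_{i,m} (W[i,] r_m)^2 / (q-1)
  bc <- drop(Minv %*% cw)
  W <- t(vapply(blocks$block_design, function(Xi) drop(Xi %*% bc), numeric(L)))
  V <- ncol(beta)
  G <- W %*% matrix(E, nrow = L)                 # q x (q*V), blocks of G_v
  gsq <- colSums(matrix(G^2, nrow = q * q))      # per-voxel ||G_v||_F^2
  variance <- gsq / (q - 1)

  new_fit(beta, drop(crossprod(beta, cw)), variance, q - 1L, "sandwich", cw,
          X, dim = dim, voxels = voxels, resid = E,
          blocks = list(q = q, block_length = L, used = blocks$used), W = W)
}

#' Cross-voxel sandwich covariance of a contrast
#'
#' Covariance between the contrast estimates of two voxels from the same
#' sandwich fit: same bread as the variance, with meat built from the
#' cross-voxel residual covariance `(q-1)^-1 sum_i r_ij r_ik'`. The
#' covariance of a voxel with itself equals its sandwich variance exactly.
#'
#' @param fit a sandwich `il_fit` (residual blocks must be present).
#' @param voxel_j,voxel_k column indices of the two voxels in the fit.
#' @return the scalar covariance estimate.
#' @export
sandwich_covariance <- function(fit, voxel_j, voxel_k) {
  check_sandwich(fit)
  g <- g_vector(fit, voxel_j)
  if (voxel_j == voxel_k) return(sum(g^2) / (fit$blocks$q - 1))
  sum(g * g_vector(fit, voxel_k)) / (fit$blocks$q - 1)
}

#' Covariances of one voxel's contrast with every voxel in the fit
#'
#' Vectorised version of [sandwich_covariance()] against a fixed reference
#' voxel, used to test all non-significant voxels against the comparison
#' voxel in one pass.
#'
#' @param fit a sandwich `il_fit`.
#' @param voxel_j reference voxel column index.
#' @return numeric vector of length V; entry `voxel_j` equals its variance.
#' @export
sandwich_covariance_all <- function(fit, voxel_j) {
  check_sandwich(fit)
  q <- fit$blocks$q; L <- fit$blocks$block_length
  Gj <- fit$W %*% matrix(fit$resid[, voxel_j], nrow = L)   # q x q
  u <- crossprod(Gj, fit$W)                                # q x L, [m, l]
  drop(as.vector(t(u)) %*% fit$resid) / (q - 1)
}

check_sandwich <- function(fit) {
  if (!inherits(fit, "il_fit") || fit$estimator != "sandwich" ||
      is.null(fit$resid)) {
    il_abort("Cross-voxel covariance needs a sandwich fit with residual blocks.",
             "inlimbo_error_spec")
  }
  invisible(fit)
}

g_vector <- function(fit, v) {
  L <- fit$blocks$block_length
  as.vector(fit$W %*% matrix(fit$resid[, v], nrow = L))
}
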