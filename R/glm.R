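# Mass-univariate GLM fits. All fitting functions accept the data as a
# T-vector (one voxel) or a T x V matrix (voxels in columns) and return an
# `il_fit` carrying per-voxel contrast estimates and variances.

new_fit <- function(beta, contrast, variance, dof, estimator, weights, design,
                    dim = NULL, voxels = NULL, resid = NULL, blocks = NULL,
                    W = NULL) {
  V <- length(contrast)
  structure(list(
    beta = beta, contrast = contrast, variance = variance, dof = dof,
    estimator = estimator, contrast_weights = as.numeric(weights),
    design = design,
    dim = dim %||% V, voxels = voxels %||% seq_len(V),
    resid = resid, blocks = blocks, W = W
  ), class = "il_fit")
}

#' @export
print.il_fit <- function(x, ...) {
  cat(sprintf("<il_fit> %s estimator, %d voxel(s), dof = %s\n",
              x$estimator, length(x$contrast), format(x$dof)))
  invisible(x)
}

as_voxel_matrix <- function(y) {
  if (is.matrix(y)) y else matrix(as.numeric(y), ncol = 1)
}

#' Ordinary least squares GLM fit
#'
#' Per-voxel OLS fit: `beta = (X'X)^-1 X'y`, residual variance
#' `RSS / (T - p)`, and `Var(c'beta) = sigma^2 c'(X'X)^-1 c`. OLS variances
#' assume independent errors and are known to be optimistic for
#' autocorrelated BOLD noise; this fit is the naive baseline the sandwich
#' estimator is compared against.
#'
#' @param y T-vector or T x V matrix of voxel time series.
#' @param design an `il_design` (or plain matrix).
#' @param contrast contrast weights (see [contrast_spec()]).
#' @return an `il_fit` with `estimator = "ols"` and `dof = T - p`.
#' @examples
#' X <- as_design(cbind(x = rnorm(20), intercept = 1))
#' f <- fit_ols(rnorm(20), X, c(1, 0))
#' @export
fit_ols <- function(y, design, contrast) {
  Y <- as_voxel_matrix(y)
  X <- if (inherits(design, "il_design")) design else as_design(design)
  if (nrow(Y) != nrow(X)) {
    il_abort("Time series length does not match the design.", "inlimbo_error_spec")
  }
  cw <- as.numeric(contrast_spec(contrast, X))
  check_full_rank(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  dof <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / dof
  cvar <- drop(t(cw) %*% XtXinv %*% cw)
  new_fit(beta, drop(crossprod(beta, cw)), s2 * cvar, dof, "ols", cw,
          new_design(unclass(X)))
}

#' Prewhitened (GLS) GLM fit with an AR noise model
#'
#' The classical alternative to OLS: an AR model of order `ar_order` is
#' fitted (Yule-Walker) to the OLS residuals of each voxel, the data and
#' design are prewhitened with the estimated coefficients, and the model is
#' refitted. For AR(1) the first observation is kept with the exact
#' `sqrt(1 - phi^2)` scaling; for higher orders the first `ar_order` rows are
#' dropped (conditional likelihood). Provided as a comparison baseline; the
#' sandwich estimator is the package default for inference.
#'
#' @inheritParams fit_ols
#' @param ar_order autoregressive order, >= 1.
#' @return an `il_fit` with `estimator = "gls_ar"`.
#' @export
fit_gls_ar <- function(y, design, contrast, ar_order = 1L) {
  ar_order <- as.integer(ar_order)
  if (ar_order < 1L) {
    il_abort("`ar_order` must be >= 1.", "inlimbo_error_spec")
  }
  Y <- as_voxel_matrix(y)
  X <- if (inherits(design, "il_design")) design else as_design(design)
  if (nrow(Y) != nrow(X)) {
    il_abort("Time series length does not match the design.", "inlimbo_error_spec")
  }
  cw <- as.numeric(contrast_spec(contrast, X))
  check_full_rank(X)
  Tn <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta0 <- XtXinv %*% crossprod(X, Y)
  res0 <- Y - X %*% beta0
  V <- ncol(Y)
  beta <- matrix(NA_real_, p, V)
  cvar <- numeric(V)
  dof <- NA_integer_
  for (v in seq_len(V)) {
    phi <- ar(res0[, v], aic = FALSE, order.max = ar_order,
              method = "yule-walker", demean = FALSE)$ar
    if (length(phi) && any(Mod(polyroot(c(1, -phi))) <= 1)) {
      il_abort(
        "Estimated AR process is non-stationary; consider the sandwich estimator.",
        "inlimbo_error_ar")
    }
    wh <- prewhiten(cbind(Y[, v], X), phi)
    yw <- wh[, 1]; Xw <- wh[, -1, drop = FALSE]
    XtXw <- chol2inv(chol(crossprod(Xw)))
    b <- XtXw %*% crossprod(Xw, yw)
    rw <- yw - Xw %*% b
    dof <- length(yw) - p
    s2 <- sum(rw^2) / dof
    beta[, v] <- b
    cvar[v] <- s2 * drop(t(cw) %*% XtXw %*% cw)
  }
  new_fit(beta, drop(crossprod(beta, cw)), cvar, dof, "gls_ar", cw,
          new_design(unclass(X)))
}

# Apply the AR quasi-differencing filter to the columns of M.
prewhiten <- function(M, phi) {
  p <- length(phi)
  if (p == 0L) return(M)
  Tn <- nrow(M)
  W <- M[(p + 1):Tn, , drop = FALSE]
  for (k in seq_len(p)) {
    W <- W - phi[k] * M[(p + 1 - k):(Tn - k), , drop = FALSE]
  }
  if (p == 1L) {
    W <- rbind(sqrt(1 - phi^2) * M[1, , drop = FALSE], W)
  }
  W
}
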