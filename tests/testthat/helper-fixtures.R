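# Shared fixture builders. Everything is generated in code; no stored data.

# A small full-rank design with a smooth "task" regressor and intercept.
toy_design <- function(T = 48, seed = 1) {
  withr::with_seed(seed, {
    ev <- data.frame(onset = seq(8, by = 24, length.out = floor(T * 2 / 24)),
                     duration = 8, condition = "task")
    build_design(ev, T, tr = 2)
  })
}

# Vectorised stationary AR(1) noise, marginal sd `sigma` (columns independent).
ar1_matrix <- function(T, V, phi, sigma = 1) {
  E <- matrix(0, T, V)
  E[1, ] <- rnorm(V)
  for (t in seq_len(T)[-1]) {
    E[t, ] <- phi * E[t - 1, ] + sqrt(1 - phi^2) * rnorm(V)
  }
  sigma * E
}

# Dense, index-by-index sandwich computation used as the independent oracle
# for fit_sandwich / sandwich_covariance (no shared code with the package's
# vectorised path beyond base R).
dense_sandwich <- function(Y, X, cw, q) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  T <- nrow(X); L <- T %/% q; used <- q * L
  idx <- split(seq_len(used), rep(seq_len(q), each = L))
  Xi <- lapply(idx, function(i) X[i, , drop = FALSE])
  M <- Reduce(`+`, lapply(Xi, crossprod))
  Minv <- solve(M)
  beta <- Minv %*% Reduce(`+`, Map(function(x, i) crossprod(x, Y[i, , drop = FALSE]),
                                   Xi, idx))
  resid <- Map(function(x, i) Y[i, , drop = FALSE] - x %*% beta, Xi, idx)
  V <- ncol(Y)
  varfun <- function(j, k) {
    S <- Reduce(`+`, lapply(resid, function(r) tcrossprod(r[, j], r[, k]))) / (q - 1)
    meat <- Reduce(`+`, lapply(Xi, function(x) t(x) %*% S %*% x))
    drop(t(cw) %*% Minv %*% meat %*% Minv %*% cw)
  }
  list(beta = beta, contrast = drop(crossprod(beta, cw)), cov = varfun)
}

# One synthetic subject analysed end to end with the frozen study settings.
recovery_run <- function(seed = 1, correction = "none", alpha = 0.05,
                         z_threshold = 4.4) {
  spec <- synthetic_spec(seed = seed)
  sub <- generate_subject(spec)
  cfg <- il_config(bold = sub$bold, design = sub$design,
                   contrast = c(task = 1), z_threshold = z_threshold, q = 28,
                   cluster_method = "grf", correction = correction,
                   alpha_limbo = alpha)
  run <- suppressMessages(run_subject(cfg))
  run$subject <- sub
  run
}
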