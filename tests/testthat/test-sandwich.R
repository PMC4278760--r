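test_that("block defaulting follows the square-root-of-T rule and drops the remainder", {
  X <- toy_design(T = 100)
  b <- make_blocks(rnorm(100), X)
  expect_equal(b$q, 10L)
  expect_equal(b$block_length, 10L)

  X3 <- as_design(cbind(x = rnorm(103), intercept = 1))
  b3 <- make_blocks(rnorm(103), X3)
  expect_equal(b3$q, 10L)
  expect_equal(b3$block_length, 10L)
  expect_equal(b3$used, 100L)            # last 3 time points dropped

  b2 <- make_blocks(rnorm(10), as_design(cbind(x = rnorm(10), intercept = 1)),
                    q = 2)
  expect_equal(b2$q, 2L)
  expect_equal(b2$block_length, 5L)
  expect_error(make_blocks(rnorm(3), as_design(cbind(x = rnorm(3)))),
               class = "inlimbo_error_spec")
})

test_that("noise-free data give zero sandwich variance and exact coefficients", {
  X <- toy_design(T = 64)
  y <- drop(unclass(X) %*% c(1.5, 2))
  f <- fit_sandwich(y, X, c(task = 1))
  expect_equal(f$contrast, 1.5, tolerance = 1e-10)
  expect_equal(f$variance, 0, tolerance = 1e-20)
  expect_equal(f$dof, f$blocks$q - 1L)
})

test_that("vectorised sandwich path equals the dense index-by-index oracle", {
  withr::with_seed(5, {
    T <- 54; q <- 6
    X <- toy_design(T = T)
    Y <- matrix(rnorm(T * 4), T)
    f <- fit_sandwich(Y, X, c(task = 1), q = q)
    o <- dense_sandwich(Y, unclass(X), c(1, 0), q)
    expect_equal(f$contrast, o$contrast, tolerance = 1e-12)
    for (v in 1:4) expect_equal(f$variance[v], o$cov(v, v), tolerance = 1e-12)
    expect_equal(sandwich_covariance(f, 1, 3), o$cov(1, 3), tolerance = 1e-12)
    expect_equal(sandwich_covariance_all(f, 2),
                 vapply(1:4, function(v) o$cov(2, v), numeric(1)),
                 tolerance = 1e-12)
  })
})

test_that("q = 2 antisymmetric residuals match the closed-form single-term sandwich", {
  # two identical blocks, residuals r and -r: Sigma_hat = 2 r r', so
  # Var = 2 * (c' Minv X' r)^2 summed over the two blocks = 4 (w'r)^2
  T <- 20; L <- 10
  Xb <- cbind(x = sin(seq_len(L)), intercept = 1)
  X <- as_design(rbind(Xb, Xb))
  beta <- c(2, 1)
  r <- scale(rnorm(L), scale = FALSE)
  r <- r - Xb %*% solve(crossprod(Xb), crossprod(Xb, r))  # orthogonal to Xb
  y <- c(Xb %*% beta + r, Xb %*% beta - r)
  f <- fit_sandwich(y, X, c(1, 0), q = 2)
  Minv <- solve(2 * crossprod(Xb))
  w <- drop(Xb %*% Minv %*% c(1, 0))
  expect_equal(f$contrast, 2, tolerance = 1e-10)
  expect_equal(f$variance, 4 * sum(w * r)^2, tolerance = 1e-10)
})

test_that("sandwich variance is invariant to block permutation", {
  withr::with_seed(9, {
    T <- 60; q <- 6; L <- 10
    X <- toy_design(T = T)
    y <- ar1_matrix(T, 1, 0.4)[, 1] + drop(unclass(X) %*% c(1, 0))
    f <- fit_sandwich(y, X, c(task = 1), q = q)
    perm <- sample(q)
    rows <- as.vector(vapply(perm, function(i) (i - 1) * L + seq_len(L),
                             numeric(L)))
    f2 <- fit_sandwich(y[rows], as_design(unclass(X)[rows, ]), c(1, 0), q = q)
    expect_equal(f2$contrast, f$contrast, tolerance = 1e-10)
    expect_equal(f2$variance, f$variance, tolerance = 1e-10)
  })
})

test_that("cross-voxel covariance is symmetric, self-consistent and PSD per pair", {
  withr::with_seed(13, {
    X <- toy_design(T = 48)
    Y <- matrix(rnorm(48 * 6), 48)
    Y[, 3] <- Y[, 2]                      # identical noise pair
    f <- fit_sandwich(Y, X, c(task = 1), q = 6)
    expect_equal(sandwich_covariance(f, 1, 4), sandwich_covariance(f, 4, 1))
    expect_equal(sandwich_covariance(f, 5, 5), f$variance[5])
    expect_equal(sandwich_covariance(f, 2, 3), f$variance[2], tolerance = 1e-12)
    for (pair in list(c(1, 2), c(4, 6), c(2, 3))) {
      S <- matrix(c(f$variance[pair[1]],
                    sandwich_covariance(f, pair[1], pair[2]),
                    sandwich_covariance(f, pair[1], pair[2]),
                    f$variance[pair[2]]), 2)
      expect_gte(min(eigen(S, symmetric = TRUE)$values), -1e-12)
    }
  })
})

test_that("independently generated voxels have mean covariance near zero (MC oracle)", {
  withr::with_seed(17, {
    X <- toy_design(T = 48)
    nmc <- 400
    covs <- numeric(nmc)
    for (r in seq_len(nmc)) {
      f <- fit_sandwich(matrix(rnorm(96), 48), X, c(task = 1), q = 6)
      covs[r] <- sandwich_covariance(f, 1, 2)
    }
    expect_lt(abs(mean(covs)), 3 * sd(covs) / sqrt(nmc))
  })
})

test_that("OLS, GLS-AR and sandwich agree in expectation on white noise", {
  withr::with_seed(29, {
    X <- toy_design(T = 80)
    nmc <- 300
    est <- matrix(NA_real_, nmc, 3)
    for (r in seq_len(nmc)) {
      y <- rnorm(80) + drop(unclass(X) %*% c(1, 0))
      est[r, ] <- c(fit_ols(y, X, c(task = 1))$contrast,
                    fit_gls_ar(y, X, c(task = 1))$contrast,
                    fit_sandwich(y, X, c(task = 1))$contrast)
    }
    se <- apply(est, 2, sd) / sqrt(nmc)
    m <- colMeans(est)
    expect_lt(abs(m[1] - m[2]), 3 * max(se))
    expect_lt(abs(m[1] - m[3]), 3 * max(se))
  })
})

test_that("covariance requires a sandwich fit with residual blocks", {
  X <- toy_design(T = 30)
  f <- fit_ols(rnorm(30), X, c(task = 1))
  expect_error(sandwich_covariance(f, 1, 1), class = "inlimbo_error_spec")
})
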