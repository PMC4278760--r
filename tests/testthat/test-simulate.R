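test_that("the same spec and seed reproduce the dataset exactly", {
  spec <- synthetic_spec(grid = c(16, 16),
                         regions = list(A = list(center = c(5, 5), radius = 2,
                                                 effect = 3)),
                         seed = 11)
  s1 <- generate_subject(spec)
  s2 <- generate_subject(spec)
  expect_identical(s1$bold, s2$bold)
  expect_identical(s1$truth, s2$truth)
  # and generation is independent of the caller's RNG state
  set.seed(999); s3 <- generate_subject(spec)
  expect_identical(s1$bold, s3$bold)
})

test_that("with zero noise the signal is exactly baseline plus scaled regressor", {
  spec <- synthetic_spec(grid = c(12, 12),
                         regions = list(A = list(center = c(6, 6), radius = 3,
                                                 effect = 2)),
                         noise = list(sigma = 0, ar = 0, spatial_fwhm = 0),
                         seed = 1)
  s <- generate_subject(spec)
  Y <- as_timeseries_matrix(s$bold)
  x <- unclass(s$design)[, "task"]
  inside <- which(as.vector(s$truth$A))
  outside <- which(!as.vector(s$truth$A))
  expect_equal(Y[, inside[1]], 100 + 2 * x)
  expect_true(all(Y[, outside] == 100))
})

test_that("background lag-1 autocorrelation matches the AR coefficient", {
  spec <- synthetic_spec(seed = 21)
  s <- generate_subject(spec)
  Y <- as_timeseries_matrix(s$bold)
  bg <- which(!(as.vector(s$truth$A) | as.vector(s$truth$B)))[1:500]
  ac <- vapply(bg, function(v) {
    e <- Y[, v] - mean(Y[, v])
    sum(head(e, -1) * tail(e, -1)) / sum(e^2)
  }, numeric(1))
  expect_lt(abs(mean(ac) - spec$noise$ar), 0.1)
})

test_that("zero jitter gives identical subjects' truth; jitter spreads it", {
  spec0 <- synthetic_spec(grid = c(32, 32),
                          regions = list(A = list(center = c(16, 16), radius = 5,
                                                  effect = 3)),
                          n_subjects = 4, seed = 2)
  g0 <- generate_group(spec0)
  for (s in g0$subjects[-1]) expect_identical(s$truth, g0$subjects[[1]]$truth)

  specj <- synthetic_spec(grid = c(32, 32),
                          regions = list(A = list(center = c(16, 16), radius = 5,
                                                  effect = 3)),
                          n_subjects = 20,
                          subject_jitter = list(center_sd = 2, radius_sd = 0,
                                                effect_sd = 0),
                          seed = 2)
  gj <- generate_group(specj)
  masks <- lapply(gj$subjects, function(s) s$truth$A)
  un <- Reduce(`|`, masks); int <- Reduce(`&`, masks)
  expect_gt(sum(un), sum(int))            # the ring structure exists
})

test_that("group generation enforces its preconditions", {
  spec <- synthetic_spec(n_subjects = 1)
  expect_error(generate_group(spec), class = "inlimbo_error_spec")
  expect_error(synthetic_spec(noise = list(sigma = 1, ar = 1, spatial_fwhm = 0)),
               class = "inlimbo_error_spec")
  expect_error(
    synthetic_spec(grid = c(10, 10),
                   regions = list(A = list(center = c(2, 2), radius = 5,
                                           effect = 1))),
    class = "inlimbo_error_spec")
})

test_that("regions overlapping after jitter error out after redraws", {
  spec <- synthetic_spec(grid = c(40, 40),
                         regions = list(A = list(center = c(18, 20), radius = 6,
                                                 effect = 3),
                                        B = list(center = c(29, 20), radius = 6,
                                                 effect = 1.5)),
                         n_subjects = 2,
                         subject_jitter = list(center_sd = 0.01, radius_sd = 0,
                                               effect_sd = 0),
                         seed = 3)
  expect_error(generate_subject(spec), class = "inlimbo_error_spec")
})

test_that("spatially smoothed noise keeps its marginal scale", {
  spec <- synthetic_spec(grid = c(32, 32), regions = list(
    A = list(center = c(16, 16), radius = 4, effect = 0.0001)),
    noise = list(sigma = 1.6, ar = 0, spatial_fwhm = 3), seed = 5)
  s <- generate_subject(spec)
  Y <- as_timeseries_matrix(s$bold)
  expect_lt(abs(sd(Y[, 2]) - 1.6) / 1.6, 0.2)
})
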