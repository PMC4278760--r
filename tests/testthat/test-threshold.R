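test_that("a field entirely below threshold yields no clusters", {
  withr::with_seed(1, z <- array(rnorm(16 * 16, 0, 0.5), c(16, 16)))
  cl <- cluster_threshold(as_zmap(z), 3, method = "none")
  expect_equal(nrow(cl$clusters), 0L)
  expect_false(any(cl$significant))
})

test_that("a compact high-z blob survives while single-voxel excursions do not", {
  withr::with_seed(2, {
    f <- inlimbo:::simulate_null_field(c(64, 64), 2)
    blob <- inlimbo:::disc_mask(c(64, 64), c(32, 32), 5.6)   # ~100 voxels
    z <- f + 8 * blob
    # plant one isolated supra-threshold voxel far from the blob
    z[5, 5] <- max(z[5, 5], 3.2)
    zm <- as_zmap(z)
    cl <- cluster_threshold(zm, 2.3, method = "permutation", smoothness = 2,
                            n_permutations = 199, seed = 42)
    expect_true(all(cl$significant[blob]))
    expect_false(cl$significant[5, 5])
    cl_grf <- cluster_threshold(zm, 2.3, method = "grf", smoothness = 2)
    expect_true(all(cl_grf$significant[blob]))
    expect_false(cl_grf$significant[5, 5])
  })
})

test_that("z = 2.3 corresponds to a one-sided uncorrected p just below 0.011", {
  p <- pnorm(2.3, lower.tail = FALSE)
  expect_lt(p, 0.0108)
  expect_gt(p, 0.0107 - 2e-4)
})

test_that("face connectivity separates diagonal neighbours; corner joins them", {
  z <- array(0, c(4, 4))
  z[1, 1] <- z[2, 2] <- 5
  lab_f <- inlimbo:::label_clusters(z > 2, "face")
  lab_c <- inlimbo:::label_clusters(z > 2, "corner")
  expect_equal(attr(lab_f, "n"), 2L)
  expect_equal(attr(lab_c, "n"), 1L)
})

test_that("the supra-threshold voxel set is monotone non-increasing in the threshold", {
  withr::with_seed(3, {
    f <- inlimbo:::simulate_null_field(c(32, 32), 2) +
      3 * inlimbo:::disc_mask(c(32, 32), c(16, 16), 5)
    zm <- as_zmap(f)
    prev <- NULL
    for (zt in c(1.5, 2.0, 2.5, 3.0)) {
      cur <- cluster_threshold(zm, zt, method = "none")$significant
      if (!is.null(prev)) expect_true(all(prev[cur]))   # cur subset of prev
      prev <- cur
    }
  })
})

test_that("smoothness estimation recovers white and FWHM-3 fields within 20%", {
  withr::with_seed(4, {
    n_fields <- 60
    est_w <- est_s <- matrix(NA_real_, n_fields, 2)
    for (i in seq_len(n_fields)) {
      Ew <- matrix(rnorm(4 * 1024), 4)
      est_w[i, ] <- estimate_smoothness(Ew, dim = c(32, 32))
      Es <- t(vapply(1:4, function(j)
        as.vector(inlimbo:::simulate_null_field(c(32, 32), 3)), numeric(1024)))
      est_s[i, ] <- estimate_smoothness(Es, dim = c(32, 32))
    }
    # white noise: lattice FWHM sqrt(2 log 2) ~ 1.18, within 20% of 1
    expect_lt(abs(mean(est_w) - 1), 0.2)
    expect_lt(abs(mean(est_s) - 3) / 3, 0.2)
  })
})

test_that("degenerate smoothness inputs error", {
  expect_error(estimate_smoothness(matrix(0, 4, 100), dim = c(10, 10)),
               class = "inlimbo_error_degenerate")
  expect_error(estimate_smoothness(matrix(rnorm(20), 4, 5), dim = 5L),
               class = "inlimbo_error_spec")
})

test_that("GRF requested without obtainable smoothness errors", {
  z <- array(rnorm(64), c(8, 8))
  expect_error(cluster_threshold(as_zmap(z), 2.3, method = "grf"),
               class = "inlimbo_error_spec")
})

test_that("an entropy-seeded permutation null records its seed", {
  withr::with_seed(5, {
    z <- array(rnorm(256), c(16, 16))
    z[8, 8] <- 4
    expect_message(
      cl <- cluster_threshold(as_zmap(z), 2.3, method = "permutation",
                              smoothness = 1, n_permutations = 49),
      "seed")
    expect_true(is.numeric(cl$seed) && length(cl$seed) == 1)
  })
})
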