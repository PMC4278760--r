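# Cluster-extent thresholding of z-maps: primary threshold at some z, then
# cluster-level inference either through the Gaussian-random-field expected
# cluster count approximation or through a simulation null of the maximum
# cluster size on smoothness-matched Gaussian fields.

#' Label connected supra-threshold components
#'
#' Face connectivity by default (4-connectivity in 2D, 6 in 3D); corner
#' connectivity additionally joins diagonal neighbours.
#'
#' @param supra logical array.
#' @param connectivity `"face"` or `"corner"`.
#' @return integer array of cluster labels (0 = below threshold), with the
#'   number of clusters as attribute `n`.
#' @keywords internal
label_clusters <- function(supra, connectivity = c("face", "corner")) {
  connectivity <- match.arg(connectivity)
  dims <- dim(supra) %||% length(supra)
  idx <- which(supra)
  lab <- array(0L, dims)
  if (!length(idx)) return(structure(lab, n = 0L))
  coords <- arrayInd(idx, .dim = dims)
  pos <- array(0L, dims)
  pos[idx] <- seq_along(idx)
  offs <- neighbour_offsets(length(dims), connectivity)
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], `+`)
    ok <- rep(TRUE, nrow(nb))
    for (d in seq_along(dims)) ok <- ok & nb[, d] >= 1 & nb[, d] <= dims[d]
    if (!any(ok)) next
    nb_lin <- as.vector((nb[ok, , drop = FALSE] - 1) %*%
                          cumprod(c(1, dims[-length(dims)]))) + 1
    hit <- pos[nb_lin] > 0L
    if (any(hit)) {
      edges[[length(edges) + 1]] <-
        cbind(which(ok)[hit], pos[nb_lin[hit]])
    }
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  structure(lab, n = comp$no)
}

neighbour_offsets <- function(D, connectivity) {
  if (connectivity == "face") {
    offs <- matrix(0L, D, D); diag(offs) <- 1L
    return(offs)
  }
  g <- as.matrix(do.call(expand.grid, rep(list(c(-1L, 0L, 1L)), D)))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  # keep one of each +/- pair
  keep <- apply(g, 1, function(r) {
    nz <- r[r != 0]; nz[1] > 0
  })
  g[keep, , drop = FALSE]
}

#' Estimate image smoothness from residuals
#'
#' Per-axis FWHM (in voxels) of the noise field, from the variance of
#' spatial first differences of the standardized residuals: for unit-variance
#' residuals, `lambda = E[(r_a - r_b)^2]` over in-mask neighbour pairs along
#' an axis, and `FWHM = sqrt(4 log 2 / lambda)`. Results are floored at one
#' voxel. Spatially white noise yields FWHM just under 1.2 voxels on the
#' lattice (lambda = 2).
#'
#' @param fit a sandwich `il_fit` with residual blocks (or any matrix of
#'   residual images, observations in rows, voxels in columns).
#' @param dim voxel grid dimensions (defaults to the fit's).
#' @param voxels linear indices of the residual columns in the grid.
#' @return numeric vector of per-axis FWHM estimates (voxels).
#' @export
estimate_smoothness <- function(fit, dim = NULL, voxels = NULL) {
  if (inherits(fit, "il_fit")) {
    if (is.null(fit$resid)) {
      il_abort("Smoothness estimation needs retained residuals.",
               "inlimbo_error_spec")
    }
    E <- fit$resid
    dims <- dim %||% fit$dim
    voxels <- voxels %||% fit$voxels
  } else {
    E <- as.matrix(fit)
    dims <- dim %||% ncol(E)
    voxels <- voxels %||% seq_len(ncol(E))
  }
  if (ncol(E) < 10L) {
    il_abort("Smoothness estimation needs at least 10 voxels.",
             "inlimbo_error_spec")
  }
  sdv <- sqrt(colMeans(E^2))
  if (any(sdv == 0)) {
    il_abort("Constant residual field: smoothness is undefined.",
             "inlimbo_error_degenerate")
  }
  Es <- sweep(E, 2, sdv, `/`)
  dims <- as.integer(dims)
  pos <- array(0L, dims)
  pos[voxels] <- seq_along(voxels)
  coords <- arrayInd(voxels, .dim = dims)
  stride <- cumprod(c(1, dims[-length(dims)]))
  fwhm <- numeric(length(dims))
  for (d in seq_along(dims)) {
    ok <- coords[, d] < dims[d]
    nb <- voxels[ok] + stride[d]
    hit <- pos[nb] > 0L
    a <- pos[voxels[ok]][hit]; b <- pos[nb][hit]
    if (!length(a)) { fwhm[d] <- NA_real_; next }
    lam <- mean(colMeans((Es[, a, drop = FALSE] - Es[, b, drop = FALSE])^2))
    fwhm[d] <- max(1, sqrt(4 * log(2) / lam))
  }
  fwhm
}

# Smoothing kernel sd (in voxels) that reproduces a target lattice FWHM for
# smoothed white noise: lambda = 2(1 - rho1), rho1 = exp(-1/(4 s^2)).
fwhm_to_sigma <- function(fwhm) {
  lam <- 4 * log(2) / fwhm^2
  rho <- 1 - lam / 2
  ifelse(rho <= 0, 0, sqrt(-1 / (4 * log(rho))))
}

# Simulate a standardized Gaussian random field with given per-axis FWHM
# (voxels) on a grid, by FFT convolution with circulant boundary.
simulate_null_field <- function(dims, fwhm) {
  dims <- as.integer(dims)
  x <- array(rnorm(prod(dims)), dims)
  sig <- fwhm_to_sigma(rep_len(fwhm, length(dims)))
  if (all(sig == 0)) return(x)
  k <- 1
  for (d in seq_along(dims)) {
    n <- dims[d]
    dist <- pmin(0:(n - 1), n - (0:(n - 1)))
    kd <- if (sig[d] == 0) as.numeric(dist == 0) else exp(-dist^2 / (2 * sig[d]^2))
    shape <- rep(1L, length(dims)); shape[d] <- n
    k <- k * array(rep(kd, each = prod(dims[seq_len(d - 1)])), dims)
  }
  k <- k / sqrt(sum(k^2))
  Re(fft(fft(x) * fft(k), inverse = TRUE)) / prod(dims)
}

# GRF expected number of clusters above u, for N in-mask voxels of
# dimension D and given per-axis FWHM.
grf_expected_clusters <- function(u, n_voxels, fwhm, D) {
  resels <- n_voxels / prod(rep_len(fwhm, D))
  resels * (4 * log(2))^(D / 2) * (2 * pi)^(-(D + 1) / 2) *
    u^(D - 1) * exp(-u^2 / 2)
}

# GRF cluster-level p for an observed cluster of k voxels. The cluster-size
# CDF is anchored at the smallest observable cluster, P(n >= 1) = 1, so a
# singleton's p equals the Euler-characteristic bound 1 - exp(-E[m]); with
# the usual un-anchored exp(-beta k^(2/D)) a singleton would look absurdly
# significant whenever the expected cluster size falls below one voxel
# (high thresholds on barely-smooth maps). In the classical regime
# (E[n] >> 1, beta small) the anchor changes nothing.
grf_cluster_p <- function(k, u, n_voxels, fwhm, D) {
  Em <- grf_expected_clusters(u, n_voxels, fwhm, D)
  En <- n_voxels * pnorm(u, lower.tail = FALSE) / Em
  beta <- (gamma(D / 2 + 1) / En)^(2 / D)
  p_ge_k <- exp(-beta * (k^(2 / D) - 1))
  1 - exp(-Em * p_ge_k)
}

#' Cluster-extent thresholding of a z-map
#'
#' Thresholds the z-map at `z_threshold`, groups supra-threshold voxels into
#' connected clusters, and assigns each cluster a family-wise p-value either
#' from Gaussian random field theory (`method = "grf"`) or from a simulation
#' null of the maximum cluster size over smoothness-matched Gaussian fields
#' (`method = "permutation"`). `method = "none"` keeps every supra-threshold
#' voxel (primary threshold only). Inference is one-sided on positive z;
#' negate the contrast for the other tail.
#'
#' @param zmap an `il_zmap`.
#' @param z_threshold primary (cluster-forming) threshold, > 0.
#' @param alpha_cluster cluster-level significance level.
#' @param method `"grf"`, `"permutation"`, or `"none"`.
#' @param connectivity `"face"` (default) or `"corner"`.
#' @param smoothness per-axis FWHM in voxels; if `NULL`, estimated from
#'   `fit` residuals when available.
#' @param fit optional sandwich `il_fit` used to estimate smoothness.
#' @param n_permutations number of null fields for `method = "permutation"`.
#' @param seed RNG seed for the simulation null; if missing one is drawn and
#'   recorded in the result.
#' @return an `il_clusters`: `significant` (logical array), `labels`
#'   (integer array over all supra-threshold clusters), `clusters` (tibble
#'   with label, size, min_z, max_z, p_cluster, significant, peak
#'   coordinates), plus the thresholding settings.
#' @export
cluster_threshold <- function(zmap, z_threshold, alpha_cluster = 0.05,
                              method = c("grf", "permutation", "none"),
                              connectivity = c("face", "corner"),
                              smoothness = NULL, fit = NULL,
                              n_permutations = 999, seed = NULL) {
  method <- match.arg(method)
  connectivity <- match.arg(connectivity)
  if (z_threshold <= 0) {
    il_abort("`z_threshold` must be positive (one-sided inference).",
             "inlimbo_error_spec")
  }
  if (alpha_cluster <= 0 || alpha_cluster >= 1) {
    il_abort("`alpha_cluster` must be in (0, 1).", "inlimbo_error_spec")
  }
  dims <- zmap$dim
  D <- sum(dims > 1)
  supra <- zmap$mask & !is.na(zmap$z) & zmap$z >= z_threshold
  lab <- label_clusters(supra, connectivity)
  n_cl <- attr(lab, "n")
  if (method != "none") {
    smoothness <- smoothness %||% (if (!is.null(fit))
      estimate_smoothness(fit) else NULL)
    if (is.null(smoothness)) {
      il_abort(paste0("Method '", method, "' needs `smoothness` or a `fit` ",
                      "with residuals to estimate it from."),
               "inlimbo_error_spec")
    }
    smoothness <- rep_len(smoothness, length(dims))[dims > 1]
  }
  null_max <- NULL
  if (method == "permutation" && n_cl > 0) {
    if (is.null(seed)) {
      seed <- sample.int(2^31 - 2, 1)
      inform(sprintf("Permutation null seeded from entropy: seed = %d.", seed))
    }
    null_max <- with_seed(seed, replicate(n_permutations, {
      f <- simulate_null_field(dims[dims > 1], smoothness)
      s <- array(FALSE, dims); s[zmap$mask] <- f[zmap$mask] >= z_threshold
      l <- label_clusters(s, connectivity)
      if (attr(l, "n") == 0L) 0L else max(tabulate(l[l > 0L]))
    }))
  }
  rows <- vector("list", n_cl)
  for (cl in seq_len(n_cl)) {
    vox <- which(lab == cl)
    k <- length(vox)
    zs <- zmap$z[vox]
    p <- switch(method,
      none = NA_real_,
      grf = grf_cluster_p(k, z_threshold, sum(zmap$mask), smoothness, D),
      permutation = (1 + sum(null_max >= k)) / (n_permutations + 1))
    peak <- vox_coords(vox[which.max(zs)], dims)
    rows[[cl]] <- tibble::tibble(
      label = cl, size = k, min_z = min(zs), max_z = max(zs),
      p_cluster = p,
      significant = if (method == "none") TRUE else p <= alpha_cluster,
      peak = list(as.integer(peak) - 1L))
  }
  clusters <- if (n_cl) dplyr::bind_rows(rows) else
    tibble::tibble(label = integer(), size = integer(), min_z = numeric(),
                   max_z = numeric(), p_cluster = numeric(),
                   significant = logical(), peak = list())
  significant <- array(FALSE, dims)
  for (cl in clusters$label[clusters$significant]) {
    significant[lab == cl] <- TRUE
  }
  structure(list(
    significant = significant, labels = lab, clusters = clusters,
    z_threshold = z_threshold, alpha_cluster = alpha_cluster, method = method,
    connectivity = connectivity, smoothness = smoothness,
    seed = seed, null_max = null_max, dim = dims
  ), class = "il_clusters")
}

#' @export
print.il_clusters <- function(x, ...) {
  cat(sprintf(
    "<il_clusters> z >= %.2f, method %s: %d cluster(s), %d significant voxel(s)\n",
    x$z_threshold, x$method, nrow(x$clusters), sum(x$significant)))
  invisible(x)
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
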