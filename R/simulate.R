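# Synthetic fMRI data with ground truth: a square 2D "brain" with two
# disc-shaped regions that activate during task blocks with different effect
# sizes, temporally autocorrelated noise, and (multi-subject mode)
# across-subject jitter of region location, size, and effect.

#' Specification of a synthetic fMRI study
#'
#' Defaults describe the single-subject recovery study: a 64 x 64 brain with
#' a strong region A (3% signal change) and a weak region B (1.5%), ten
#' 20 s task blocks alternating with 20 s rest at TR 2 s (200 volumes), and
#' AR(1) noise with lag-1 autocorrelation 0.3 and marginal standard
#' deviation 1.6 (in percent-of-baseline units, baseline 100). Multi-subject
#' variability is controlled by `subject_jitter` (standard deviations of the
#' per-subject perturbations of region centre, radius, and effect size).
#'
#' @param grid 2D grid dimensions.
#' @param regions named list of regions, each `list(center, radius, effect)`
#'   with `effect` in percent signal change.
#' @param design list: `n_blocks`, `block_duration`, `rest_duration`
#'   (seconds), `tr`.
#' @param noise list: `sigma` (marginal SD), `ar` (lag-1 coefficient in
#'   `[0, 1)`), `spatial_fwhm` (voxels; 0 = spatially white).
#' @param baseline baseline signal level.
#' @param n_subjects number of subjects.
#' @param subject_jitter list: `center_sd` (voxels), `radius_sd` (voxels),
#'   `effect_sd` (percent points).
#' @param seed root RNG seed; every draw derives from it.
#' @return an `il_spec` list.
#' @export
synthetic_spec <- function(grid = c(64, 64),
                           regions = list(
                             A = list(center = c(21, 21), radius = 6, effect = 3),
                             B = list(center = c(44, 44), radius = 6, effect = 1.5)),
                           design = list(n_blocks = 10, block_duration = 20,
                                         rest_duration = 20, tr = 2),
                           noise = list(sigma = 1.6, ar = 0.3, spatial_fwhm = 0),
                           baseline = 100,
                           n_subjects = 1,
                           subject_jitter = list(center_sd = 0, radius_sd = 0,
                                                 effect_sd = 0),
                           seed = 42L) {
  spec <- list(grid = as.integer(grid), regions = regions, design = design,
               noise = noise, baseline = baseline,
               n_subjects = as.integer(n_subjects),
               subject_jitter = subject_jitter, seed = as.integer(seed))
  validate_spec(spec)
  structure(spec, class = "il_spec")
}

validate_spec <- function(spec) {
  if (spec$noise$ar < 0 || spec$noise$ar >= 1) {
    il_abort("AR coefficient must be in [0, 1).", "inlimbo_error_spec")
  }
  for (nm in names(spec$regions)) {
    r <- spec$regions[[nm]]
    if (any(r$center - r$radius < 1) || any(r$center + r$radius > spec$grid)) {
      il_abort(sprintf("Region %s does not fit inside the grid.", nm),
               "inlimbo_error_spec")
    }
  }
  invisible(spec)
}

#' Number of volumes implied by a synthetic design
#' @param spec an `il_spec`.
#' @return integer T.
#' @export
spec_n_timepoints <- function(spec) {
  d <- spec$design
  as.integer(d$n_blocks * (d$block_duration + d$rest_duration) / d$tr)
}

#' Event table of the synthetic block design
#' @param spec an `il_spec`.
#' @return tibble with onset, duration, condition.
#' @export
spec_events <- function(spec) {
  d <- spec$design
  tibble::tibble(
    onset = d$rest_duration +
      (seq_len(d$n_blocks) - 1) * (d$block_duration + d$rest_duration),
    duration = d$block_duration,
    condition = "task")
}

#' Design matrix of the synthetic study
#' @param spec an `il_spec`.
#' @param hrf an [hrf_model()].
#' @return an `il_design` with columns task, intercept.
#' @export
spec_design <- function(spec, hrf = hrf_model()) {
  build_design(spec_events(spec), spec_n_timepoints(spec), spec$design$tr,
               hrf = hrf)
}

disc_mask <- function(grid, center, radius) {
  x <- matrix(seq_len(grid[1]), grid[1], grid[2])
  y <- matrix(seq_len(grid[2]), grid[1], grid[2], byrow = TRUE)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

# Draw one subject's jittered region geometry; redraw on overlapping discs.
draw_regions <- function(spec, subject_index) {
  j <- spec$subject_jitter
  base <- spec$regions
  jitter_seed <- il_child_seed(spec$seed, 2, subject_index)
  with_seed(jitter_seed, {
    for (attempt in seq_len(100)) {
      regs <- lapply(base, function(r) {
        list(center = r$center + rnorm(2, 0, j$center_sd),
             radius = max(1, r$radius + rnorm(1, 0, j$radius_sd)),
             effect = max(0, r$effect + rnorm(1, 0, j$effect_sd)))
      })
      ok <- TRUE
      nm <- names(regs)
      if (length(regs) > 1) {
        for (a in seq_along(regs)[-1]) for (b in seq_len(a - 1)) {
          dist <- sqrt(sum((regs[[a]]$center - regs[[b]]$center)^2))
          if (dist <= regs[[a]]$radius + regs[[b]]$radius) ok <- FALSE
        }
      }
      if (ok) return(regs)
    }
    il_abort("Jittered regions still overlap after 100 redraws.",
             "inlimbo_error_spec")
  })
}

#' Generate one synthetic subject
#'
#' BOLD = baseline + effect x HRF-convolved boxcar inside each region +
#' AR(1) Gaussian noise (optionally spatially smoothed, rescaled to keep the
#' marginal SD at `sigma`). Subject-level jitter of the regions is drawn
#' from a per-subject substream of the root seed, so any subject can be
#' regenerated independently and reproducibly.
#'
#' @param spec an `il_spec`.
#' @param subject_index subject number (>= 1).
#' @return a list: `bold` (array grid x T), `truth` (named list of logical
#'   region masks), `regions` (jittered geometry), `design` (`il_design`),
#'   `spec`, `subject_index`.
#' @export
generate_subject <- function(spec, subject_index = 1L) {
  validate_spec(spec)
  Tn <- spec_n_timepoints(spec)
  X <- spec_design(spec)
  x <- unclass(X)[, "task"]
  grid <- spec$grid
  V <- prod(grid)
  regs <- draw_regions(spec, subject_index)
  signal <- matrix(0, Tn, V)
  truth <- list()
  for (nm in names(regs)) {
    m <- disc_mask(grid, regs[[nm]]$center, regs[[nm]]$radius)
    truth[[nm]] <- m
    amp <- spec$baseline * regs[[nm]]$effect / 100
    signal[, as.vector(m)] <- signal[, as.vector(m)] + amp * x
  }
  noise_seed <- il_child_seed(spec$seed, 1, subject_index)
  E <- with_seed(noise_seed, ar1_noise(Tn, V, spec$noise$sigma, spec$noise$ar))
  if (spec$noise$spatial_fwhm > 0) {
    sig <- fwhm_to_sigma(spec$noise$spatial_fwhm)
    for (t in seq_len(Tn)) {
      f <- simulate_smooth_frame(matrix(E[t, ], grid[1], grid[2]), sig)
      E[t, ] <- as.vector(f)
    }
  }
  bold <- spec$baseline + signal + E
  list(bold = array(t(bold), c(grid, Tn)), truth = truth, regions = regs,
       design = X, spec = spec, subject_index = as.integer(subject_index))
}

# Stationary AR(1) noise, marginal sd sigma, T x V.
ar1_noise <- function(Tn, V, sigma, phi) {
  E <- matrix(0, Tn, V)
  E[1, ] <- rnorm(V, 0, sigma)
  if (Tn > 1) {
    innov_sd <- sigma * sqrt(1 - phi^2)
    for (t in 2:Tn) E[t, ] <- phi * E[t - 1, ] + rnorm(V, 0, innov_sd)
  }
  E
}

# Smooth one frame with a circulant Gaussian kernel, rescaled to preserve
# the marginal variance of white input.
simulate_smooth_frame <- function(frame, sig) {
  dims <- dim(frame)
  k <- 1
  for (d in seq_along(dims)) {
    n <- dims[d]
    dist <- pmin(0:(n - 1), n - (0:(n - 1)))
    kd <- exp(-dist^2 / (2 * sig^2))
    k <- k * array(rep(kd, each = prod(dims[seq_len(d - 1)])), dims)
  }
  k <- k / sqrt(sum(k^2))
  Re(fft(fft(frame) * fft(k), inverse = TRUE)) / prod(dims)
}

#' Generate a multi-subject synthetic dataset
#'
#' Every subject gets independently jittered regions and independent noise;
#' the group truth records, per voxel, how many subjects' regions cover it.
#'
#' @param spec an `il_spec` with `n_subjects >= 2`.
#' @return an `il_dataset`: `subjects` (list of [generate_subject()]
#'   results), `coverage` (named list of integer arrays, per region),
#'   `design`, `spec`.
#' @export
generate_group <- function(spec) {
  validate_spec(spec)
  if (spec$n_subjects < 2) {
    il_abort("A group dataset needs n_subjects >= 2.", "inlimbo_error_spec")
  }
  subjects <- lapply(seq_len(spec$n_subjects), function(i)
    generate_subject(spec, i))
  coverage <- lapply(names(spec$regions), function(nm) {
    Reduce(`+`, lapply(subjects, function(s) s$truth[[nm]] + 0L))
  })
  names(coverage) <- names(spec$regions)
  structure(list(subjects = subjects, coverage = coverage,
                 design = subjects[[1]]$design, spec = spec),
            class = "il_dataset")
}

#' Flatten a BOLD array to a time-by-voxel matrix
#'
#' @param bold array with time as the last dimension.
#' @return T x V matrix (voxels in array order).
#' @export
as_timeseries_matrix <- function(bold) {
  d <- dim(bold)
  Tn <- d[length(d)]
  t(matrix(bold, prod(d[-length(d)]), Tn))
}
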