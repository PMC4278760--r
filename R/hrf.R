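#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF used throughout the package: a positive gamma density
#' peaking 6 s after stimulus onset minus a 1/6-scaled undershoot gamma
#' peaking around 16 s (shape 6 and 16, rate 1 per second). The kernel is
#' evaluated on a fine grid (`tr / oversampling`) so that convolution with a
#' boxcar is accurate even for a coarse TR.
#'
#' @param kind kernel family; only `"canonical_double_gamma"` is provided.
#' @param oversampling integer >= 1, number of kernel samples per TR.
#' @param duration kernel support in seconds.
#' @return an object of class `il_hrf`.
#' @examples
#' h <- hrf_model()
#' k <- hrf_kernel(h, tr = 2)
#' @export
hrf_model <- function(kind = "canonical_double_gamma", oversampling = 16L,
                      duration = 32) {
  kind <- match.arg(kind)
  oversampling <- as.integer(oversampling)
  if (oversampling < 1L) {
    il_abort("`oversampling` must be a positive integer.", "inlimbo_error_spec")
  }
  structure(list(kind = kind, oversampling = oversampling, duration = duration),
            class = "il_hrf")
}

#' Evaluate the HRF kernel on the oversampled grid
#'
#' @param hrf an [hrf_model()].
#' @param tr repetition time in seconds.
#' @return numeric vector of kernel values at spacing `tr / oversampling`.
#' @export
hrf_kernel <- function(hrf, tr) {
  dt <- tr / hrf$oversampling
  tt <- seq(0, hrf$duration, by = dt)
  k <- dgamma(tt, shape = 6, rate = 1) - dgamma(tt, shape = 16, rate = 1) / 6
  k
}

# Convolve a per-condition boxcar (onsets/durations in seconds) with the HRF
# and sample at the TR grid. Returns a length-T column scaled to unit peak
# over the sampled support (so effect sizes are in units of peak response).
hrf_regressor <- function(onsets, durations, n_timepoints, tr, hrf) {
  os <- hrf$oversampling
  dt <- tr / os
  n_fine <- n_timepoints * os
  t_fine <- (seq_len(n_fine) - 1) * dt
  box <- numeric(n_fine)
  durations <- rep_len(durations, length(onsets))
  for (i in seq_along(onsets)) {
    on <- onsets[i]
    box[t_fine >= on & t_fine < on + durations[i]] <- 1
  }
  k <- hrf_kernel(hrf, tr)
  x <- convolve(box, rev(k), type = "open")[seq_len(n_fine)] * dt
  x[t_fine < min(onsets)] <- 0   # FFT round-off must not break causality
  x <- x[seq(1, n_fine, by = os)]
  pk <- max(abs(x))
  if (pk > 0) x <- x / pk
  x
}
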