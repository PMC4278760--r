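#' @importFrom rlang abort warn inform %||%
#' @importFrom stats pnorm qnorm pt qt rnorm sd var convolve dgamma fft
#'   p.adjust ar complete.cases
#' @importFrom utils head modifyList
NULL

# Internal error helper: all package conditions carry class "inlimbo_error"
# plus a specific subclass, so callers can catch precisely.
il_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "inlimbo_error"), ...)
}

#' Derive a reproducible child seed from a root seed
#'
#' Substreams are derived with a fixed multiplicative congruential step so
#' that (root seed, purpose, index) always maps to the same 31-bit seed,
#' independent of the caller's RNG state. Used for per-subject noise streams
#' and for internally seeded permutation nulls.
#'
#' @param seed root integer seed.
#' @param purpose small integer namespace (1 = subject noise, 2 = jitter,
#'   3 = permutation null, ...).
#' @param index stream index within the namespace.
#' @return an integer in `[1, 2^31 - 2]`.
#' @keywords internal
il_child_seed <- function(seed, purpose, index = 0L) {
  m <- 2147483647              # 2^31 - 1 (prime)
  s <- (as.double(seed) %% m)
  # three Lehmer steps, mixing in purpose and index between steps
  for (k in c(purpose, index, 0)) {
    s <- (s * 48271 + k + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Convert t-statistics to z-scores through the probability integral
# transform, using log-tail probabilities so very large |t| stay finite
# and monotone instead of collapsing to +/-Inf.
t_to_z <- function(t, dof) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  z[pos] <- qnorm(pt(t[pos], dof, lower.tail = FALSE, log.p = TRUE),
                  lower.tail = FALSE, log.p = TRUE)
  z[!pos] <- qnorm(pt(t[!pos], dof, lower.tail = TRUE, log.p = TRUE),
                   lower.tail = TRUE, log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}

# Voxel linear index <-> array index helpers (1-based internally; the
# user-facing tables also report 0-based (i,j,k) in array order).
vox_coords <- function(idx, dim) {
  arrayInd(idx, .dim = dim)
}
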