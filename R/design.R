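#' Build a first-level fMRI design matrix
#'
#' Turns per-condition event lists (onsets and durations in seconds) into a
#' design matrix of expected haemodynamic responses: each condition is a
#' boxcar of neural activity convolved with the canonical HRF, sampled at the
#' TR grid, followed by any nuisance columns. Column order is conditions
#' first (in the order given), then nuisance regressors.
#'
#' @param events a data frame with columns `onset`, `duration`, `condition`
#'   (onsets/durations in seconds), or `NULL` for a nuisance-only design.
#' @param n_timepoints number of volumes T.
#' @param tr repetition time in seconds.
#' @param hrf an [hrf_model()].
#' @param nuisance optional numeric T x k matrix appended after the condition
#'   columns (e.g. an intercept, drift terms, motion parameters).
#' @param intercept add a leading constant column (default `TRUE`); the
#'   constant counts as a nuisance regressor and is placed last.
#' @return an `il_design`: the T x p numeric matrix with attributes
#'   `regressor_names`, `conditions` and `tr`.
#' @examples
#' ev <- data.frame(onset = c(0, 40), duration = 20, condition = "task")
#' X <- build_design(ev, n_timepoints = 50, tr = 2)
#' @export
build_design <- function(events, n_timepoints, tr, hrf = hrf_model(),
                         nuisance = NULL, intercept = TRUE) {
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 2L) {
    il_abort("`n_timepoints` must be at least 2.", "inlimbo_error_spec")
  }
  cols <- list()
  conditions <- character(0)
  if (!is.null(events) && nrow(events) > 0) {
    need <- c("onset", "duration", "condition")
    if (!all(need %in% names(events))) {
      il_abort("`events` needs columns onset, duration, condition.",
               "inlimbo_error_spec")
    }
    total <- n_timepoints * tr
    if (any(events$onset < 0 | events$onset >= total)) {
      il_abort("Event onsets must lie in [0, T * tr).", "inlimbo_error_spec")
    }
    if (any(events$duration <= 0)) {
      il_abort("Event durations must be positive.", "inlimbo_error_spec")
    }
    conditions <- unique(as.character(events$condition))
    for (cn in conditions) {
      ev <- events[events$condition == cn, , drop = FALSE]
      cols[[cn]] <- hrf_regressor(ev$onset, ev$duration, n_timepoints, tr, hrf)
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = n_timepoints, ncol = 0)
  nm <- conditions
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_timepoints) {
      il_abort("`nuisance` must have T rows.", "inlimbo_error_spec")
    }
    nn <- colnames(nuisance) %||% paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
    nm <- c(nm, nn)
  }
  if (intercept) {
    X <- cbind(X, 1)
    nm <- c(nm, "intercept")
  }
  if (ncol(X) == 0L) {
    il_abort("Design has no columns; give events, nuisance or an intercept.",
             "inlimbo_error_spec")
  }
  colnames(X) <- nm
  check_full_rank(X)
  new_design(X, conditions = conditions, tr = tr)
}

new_design <- function(values, conditions = character(0), tr = NA_real_) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("x", seq_len(ncol(values)))
  }
  structure(values,
            conditions = conditions,
            regressor_names = colnames(values),
            tr = tr,
            class = c("il_design", "matrix", "array"))
}

#' Coerce a plain matrix to a design matrix
#'
#' @param values T x p numeric matrix (a pre-built design, e.g. read from a
#'   TSV file).
#' @param tr repetition time in seconds (metadata only).
#' @return an `il_design`.
#' @export
as_design <- function(values, tr = NA_real_) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) {
    il_abort("Design matrix contains non-finite entries.", "inlimbo_error_spec")
  }
  if (nrow(values) <= ncol(values)) {
    il_abort("Design must have more time points than regressors.",
             "inlimbo_error_spec")
  }
  check_full_rank(values)
  new_design(values, tr = tr)
}

# Error naming the collinear columns, per the design contract.
check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    il_abort(
      paste0("Design matrix is rank deficient; collinear column(s): ",
             paste(bad, collapse = ", ")),
      "inlimbo_error_rank")
  }
  invisible(X)
}

#' Contrast specification
#'
#' A contrast is a length-p weight vector `c` over the design columns;
#' `c'beta` is the effect tested. Weights can be given as a full numeric
#' vector or as a named vector over a design's columns (unnamed columns get
#' weight 0).
#'
#' @param weights numeric weight vector, or named numeric vector.
#' @param design optional `il_design` used to resolve names / check length.
#' @return numeric contrast vector of class `il_contrast`.
#' @examples
#' X <- as_design(cbind(task = c(0, 1, 0, 1), intercept = 1))
#' contrast_spec(c(task = 1), X)
#' @export
contrast_spec <- function(weights, design = NULL) {
  if (!is.null(names(weights)) && !is.null(design)) {
    w <- stats::setNames(numeric(ncol(design)), colnames(design))
    unknown <- setdiff(names(weights), colnames(design))
    if (length(unknown)) {
      il_abort(paste0("Unknown regressor(s) in contrast: ",
                      paste(unknown, collapse = ", ")), "inlimbo_error_spec")
    }
    w[names(weights)] <- weights
    weights <- w
  }
  weights <- as.numeric(weights)
  if (!is.null(design) && length(weights) != ncol(design)) {
    il_abort("Contrast length does not match the number of regressors.",
             "inlimbo_error_spec")
  }
  if (all(weights == 0)) {
    il_abort("Contrast weights must not all be zero.", "inlimbo_error_spec")
  }
  structure(weights, class = "il_contrast")
}
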