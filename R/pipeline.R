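# End-to-end drivers: GLM -> threshold -> comparison voxel -> limbo labels,
# for one subject or a group, plus a threshold sweep that reports per-class
# volumes the way activation tables are usually printed (cm^3).

#' Pipeline configuration
#'
#' Collects every knob of the four-step pipeline. Inputs may be file paths
#' (NIfTI / TSV) or in-memory objects; every run can write a resolved copy
#' of its configuration beside its outputs so results are reproducible from
#' the sidecar alone.
#'
#' @param bold 4D BOLD NIfTI path, or an array with time last.
#' @param mask 3D mask path or logical array; `NULL` analyses all voxels.
#' @param events events TSV path or data frame (onset, duration, condition).
#' @param design pre-built design TSV path, matrix, or `NULL` to build from
#'   `events`.
#' @param contrast contrast weights (named or positional; see
#'   [contrast_spec()]).
#' @param tr repetition time in seconds (needed when building from events).
#' @param z_threshold primary cluster-forming threshold.
#' @param alpha_cluster cluster-level alpha.
#' @param alpha_limbo one-sided alpha of the in-limbo test.
#' @param q number of replication blocks (`NULL`: `floor(sqrt(T))`).
#' @param estimator `"sandwich"` (required for the limbo test).
#' @param cluster_method `"grf"`, `"permutation"`, or `"none"`.
#' @param n_permutations null fields for the permutation method.
#' @param smoothness per-axis FWHM in voxels; `NULL` estimates from
#'   residuals.
#' @param correction `"none"` or `"fdr"` for the limbo p-values.
#' @param seed RNG seed (permutation null).
#' @param level `"subject"` or `"group"`.
#' @param voxel_size voxel dimensions in mm (volume reporting); read from
#'   the NIfTI header when available.
#' @param output_dir directory for output maps; `NULL` keeps results in
#'   memory only.
#' @return an `il_config` list.
#' @export
il_config <- function(bold = NULL, mask = NULL, events = NULL, design = NULL,
                      contrast = c(task = 1), tr = NULL,
                      z_threshold = 2.3, alpha_cluster = 0.05,
                      alpha_limbo = 0.05, q = NULL, estimator = "sandwich",
                      cluster_method = "grf", n_permutations = 999,
                      smoothness = NULL, correction = "none", seed = NULL,
                      level = "subject", voxel_size = c(1, 1, 1),
                      output_dir = NULL) {
  structure(as.list(environment()), class = "il_config")
}

config_json <- function(config) {
  ser <- lapply(unclass(config), function(x) {
    if (is.null(x) || is.character(x) || is.numeric(x) || is.logical(x)) x
    else sprintf("<in-memory %s>", class(x)[1])
  })
  jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

#' Write / read a configuration sidecar
#' @param config an `il_config`.
#' @param path JSON file path.
#' @return `path` (write) or an `il_config` (read).
#' @export
write_config <- function(config, path) {
  writeLines(config_json(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(il_config, x[!vapply(x, is.null, logical(1))])
}

load_bold <- function(config) {
  if (is.character(config$bold)) {
    img <- read_nifti_image(config$bold)
    list(bold = drop_singleton(img), ref = img,
         voxel_size = utils::head(RNifti::pixdim(img), 3))
  } else {
    list(bold = drop_singleton(config$bold), ref = NULL,
         voxel_size = config$voxel_size)
  }
}

# Drop singleton spatial dimensions (a 2D slice stored as X x Y x 1 x T)
# for analysis; outputs are written back at the stored shape.
drop_singleton <- function(bold) {
  d <- dim(bold)
  spatial <- d[-length(d)]
  keep <- spatial > 1
  if (all(keep)) return(array(as.numeric(bold), d))
  array(as.numeric(bold), c(spatial[keep], d[length(d)]))
}

load_mask <- function(config, dims) {
  if (is.null(config$mask)) return(array(TRUE, dims))
  m <- if (is.character(config$mask)) {
    as.array(read_nifti_image(config$mask)) > 0
  } else {
    config$mask
  }
  m <- array(as.logical(m)[seq_len(prod(dims))], dims)
  m
}

resolve_design <- function(config, n_timepoints) {
  if (!is.null(config$design)) {
    X <- if (is.character(config$design)) read_design_tsv(config$design,
                                                         config$tr %||% NA_real_)
         else if (inherits(config$design, "il_design")) config$design
         else as_design(config$design, config$tr %||% NA_real_)
  } else if (!is.null(config$events)) {
    ev <- if (is.character(config$events)) read_events_tsv(config$events)
          else config$events
    if (is.null(config$tr)) {
      il_abort("`tr` is required to build a design from events.",
               "inlimbo_error_spec")
    }
    X <- build_design(ev, n_timepoints, config$tr)
  } else {
    il_abort("Provide `design` or `events`.", "inlimbo_error_spec")
  }
  if (nrow(X) != n_timepoints) {
    il_abort(sprintf("Design has %d rows but the BOLD series has %d volumes.",
                     nrow(X), n_timepoints), "inlimbo_error_spec")
  }
  X
}

fit_subject <- function(config, bold_in = NULL) {
  inp <- if (is.null(bold_in)) load_bold(config) else bold_in
  bold <- inp$bold
  d <- dim(bold)
  dims <- d[-length(d)]
  Tn <- d[length(d)]
  mask <- load_mask(config, dims)
  Y <- as_timeseries_matrix(bold)
  vox <- which(as.vector(mask))
  X <- resolve_design(config, Tn)
  fit <- fit_sandwich(Y[, vox, drop = FALSE], X, config$contrast,
                      q = config$q, dim = dims, voxels = vox)
  list(fit = fit, mask = mask, dims = dims, ref = inp$ref,
       voxel_size = inp$voxel_size)
}

#' Run the single-subject pipeline
#'
#' Executes the four steps — sandwich GLM, cluster thresholding of the
#' z-map, comparison-voxel selection, in-limbo classification — and
#' (optionally) writes every map plus a resolved-config sidecar to
#' `config$output_dir`.
#'
#' @param config an [il_config()].
#' @return an `il_run` list: `limbo`, `zmap`, `clusters`, `fit`,
#'   `comparison`, `config`, `voxel_size`.
#' @export
run_subject <- function(config) {
  fs <- fit_subject(config)
  zmap <- contrast_zmap(fs$fit)
  zmap$pixdim <- fs$voxel_size
  clusters <- cluster_threshold(
    zmap, config$z_threshold, config$alpha_cluster,
    method = config$cluster_method, smoothness = config$smoothness,
    fit = fs$fit, n_permutations = config$n_permutations, seed = config$seed)
  limbo <- classify_brain(zmap, clusters, fs$fit, alpha = config$alpha_limbo,
                          correction = config$correction)
  run <- structure(list(limbo = limbo, zmap = zmap, clusters = clusters,
                        fit = fs$fit, comparison = limbo$comparison,
                        config = config, voxel_size = fs$voxel_size,
                        ref = fs$ref),
                   class = "il_run")
  maybe_write_run(run)
  run
}

#' Run the group-level pipeline
#'
#' Fits every subject with the sandwich estimator, forms the level-2 z-map
#' from the per-subject contrasts (one-sample t across subjects), thresholds
#' it, selects the comparison voxel on the group map, and applies the WLS
#' in-limbo test per voxel with per-subject precision weights.
#'
#' @param config an [il_config()] with the shared analysis settings.
#' @param subjects list of per-subject BOLD inputs (paths or arrays on a
#'   common grid).
#' @return an `il_run` with the group `limbo` result and `fits` (per
#'   subject).
#' @export
run_group <- function(config, subjects) {
  if (length(subjects) < 2) {
    il_abort("Group analysis needs at least 2 subjects.", "inlimbo_error_spec")
  }
  fits <- vector("list", length(subjects))
  fs1 <- NULL
  for (i in seq_along(subjects)) {
    ci <- config
    ci$bold <- subjects[[i]]
    fs <- fit_subject(ci)
    if (is.null(fs1)) fs1 <- fs
    if (!identical(fs$dims, fs1$dims)) {
      il_abort("Subjects have mismatched grids.", "inlimbo_error_spec")
    }
    fits[[i]] <- fs$fit
  }
  C <- do.call(rbind, lapply(fits, function(f) f$contrast))
  zmap <- group_zmap(C, dim = fs1$dims, voxels = fits[[1]]$voxels,
                     mask = fs1$mask)
  zmap$pixdim <- fs1$voxel_size
  clusters <- cluster_threshold(
    zmap, config$z_threshold, config$alpha_cluster,
    method = config$cluster_method,
    smoothness = config$smoothness %||% estimate_smoothness(fits[[1]]),
    n_permutations = config$n_permutations, seed = config$seed)
  limbo <- classify_group(zmap, clusters, fits, alpha = config$alpha_limbo,
                          correction = config$correction)
  run <- structure(list(limbo = limbo, zmap = zmap, clusters = clusters,
                        fits = fits, comparison = limbo$comparison,
                        config = config, voxel_size = fs1$voxel_size,
                        ref = fs1$ref),
                   class = "il_run")
  maybe_write_run(run)
  run
}

#' @export
print.il_run <- function(x, ...) {
  print(x$limbo)
  invisible(x)
}

maybe_write_run <- function(run) {
  dir <- run$config$output_dir
  if (is.null(dir)) return(invisible(run))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- run$ref
  shape <- function(a) if (is.null(ref)) a else array(a, dim(ref)[-length(dim(ref))])
  if (!is.null(run$fit)) {
    write_nifti_map(shape(fit_map(run$fit, "contrast")), file.path(dir, "contrast.nii"), ref)
    write_nifti_map(shape(fit_map(run$fit, "variance")), file.path(dir, "variance.nii"), ref)
    for (k in seq_len(nrow(run$fit$beta))) {
      bk <- array(NA_real_, run$fit$dim)
      bk[run$fit$voxels] <- run$fit$beta[k, ]
      nm <- colnames(run$fit$design)[k] %||% paste0("regressor", k)
      write_nifti_map(shape(bk), file.path(dir, sprintf("beta_%s.nii", nm)), ref)
    }
  }
  write_nifti_map(shape(run$zmap$z), file.path(dir, "zmap.nii"), ref)
  write_nifti_map(shape(run$clusters$labels), file.path(dir, "cluster_labels.nii"), ref)
  write_nifti_map(shape(run$limbo$labels), file.path(dir, "labels.nii"), ref)
  write_nifti_map(shape(run$limbo$t_limbo), file.path(dir, "t_limbo.nii"), ref)
  write_nifti_map(shape(run$limbo$p_limbo), file.path(dir, "p_limbo.nii"), ref)
  write_cluster_tsv(run$clusters, file.path(dir, "clusters.tsv"))
  write_config(run$config, file.path(dir, "config.json"))
  summ <- list(comparison = run$comparison[c("index", "coords", "z")],
               counts = as.list(limbo_counts(run$limbo)),
               volumes_cm3 = as.list(class_volumes(run$limbo, run$voxel_size)))
  writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "summary.json"))
  invisible(run)
}

fit_map <- function(fit, what) {
  out <- array(NA_real_, fit$dim)
  out[fit$voxels] <- fit[[what]]
  out
}

class_volumes <- function(limbo, voxel_size = c(1, 1, 1)) {
  vv <- prod(voxel_size) / 1000        # mm^3 -> cm^3
  n <- limbo_counts(limbo)
  n[c("activated", "in_limbo", "less")] * vv
}

#' Sweep the cluster-forming threshold
#'
#' Reruns thresholding and limbo classification for each z-threshold and
#' tabulates per-class volumes (cm^3, from the voxel dimensions) plus the
#' comparison voxel chosen at each threshold — the quantity behind the
#' observation that the in-limbo volume need not shrink as the threshold
#' rises. Thresholds with an empty significant set yield a flagged row, not
#' an error.
#'
#' @param config an [il_config()].
#' @param z_thresholds numeric vector of primary thresholds.
#' @param subjects optional list of subject inputs for `level = "group"`.
#' @return tibble: one row per threshold with volumes, counts, the
#'   comparison voxel and an `empty` flag.
#' @export
threshold_sweep <- function(config, z_thresholds, subjects = NULL) {
  fs <- NULL; fits <- NULL; zmap <- NULL
  if (identical(config$level, "group")) {
    base <- run_group_parts(config, subjects)
    zmap <- base$zmap; fits <- base$fits; fs <- base$fs1
  } else {
    fs <- fit_subject(config)
    zmap <- contrast_zmap(fs$fit)
    zmap$pixdim <- fs$voxel_size
  }
  rows <- lapply(z_thresholds, function(zt) {
    res <- tryCatch({
      clusters <- cluster_threshold(
        zmap, zt, config$alpha_cluster, method = config$cluster_method,
        smoothness = config$smoothness %||%
          estimate_smoothness(if (is.null(fits)) fs$fit else fits[[1]]),
        n_permutations = config$n_permutations, seed = config$seed)
      limbo <- if (is.null(fits)) {
        classify_brain(zmap, clusters, fs$fit, alpha = config$alpha_limbo,
                       correction = config$correction)
      } else {
        classify_group(zmap, clusters, fits, alpha = config$alpha_limbo,
                       correction = config$correction)
      }
      vols <- class_volumes(limbo, fs$voxel_size)
      counts <- limbo_counts(limbo)
      tibble::tibble(
        z_threshold = zt,
        n_activated = counts[["activated"]],
        n_in_limbo = counts[["in_limbo"]],
        n_less = counts[["less"]],
        vol_activated_cm3 = vols[["activated"]],
        vol_in_limbo_cm3 = vols[["in_limbo"]],
        vol_less_cm3 = vols[["less"]],
        comparison_voxel = paste(limbo$comparison$coords, collapse = ","),
        comparison_z = limbo$comparison$z,
        empty = FALSE)
    }, inlimbo_error_no_significant = function(e) {
      tibble::tibble(z_threshold = zt, n_activated = 0L, n_in_limbo = 0L,
                     n_less = 0L, vol_activated_cm3 = 0,
                     vol_in_limbo_cm3 = 0, vol_less_cm3 = 0,
                     comparison_voxel = NA_character_,
                     comparison_z = NA_real_, empty = TRUE)
    })
    res
  })
  dplyr::bind_rows(rows)
}

run_group_parts <- function(config, subjects) {
  fits <- vector("list", length(subjects)); fs1 <- NULL
  for (i in seq_along(subjects)) {
    ci <- config; ci$bold <- subjects[[i]]
    fs <- fit_subject(ci)
    if (is.null(fs1)) fs1 <- fs
    fits[[i]] <- fs$fit
  }
  C <- do.call(rbind, lapply(fits, function(f) f$contrast))
  zmap <- group_zmap(C, dim = fs1$dims, voxels = fits[[1]]$voxels,
                     mask = fs1$mask)
  zmap$pixdim <- fs1$voxel_size
  list(zmap = zmap, fits = fits, fs1 = fs1)
}
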