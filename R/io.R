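# NIfTI-1 and delimited-text I/O. All images are read and written through
# RNifti so the source affine/header travels with every derived map.

#' Read a 4D BOLD series or 3D image
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @return an `RNifti` image (array with NIfTI attributes).
#' @export
read_nifti_image <- function(path) {
  if (!file.exists(path)) {
    il_abort(sprintf("File not found: %s", path), "inlimbo_error_io")
  }
  RNifti::readNifti(path)
}

#' Write a derived map with the affine of a reference image
#'
#' @param data numeric/integer array.
#' @param path destination file.
#' @param reference image (or path) whose header/affine is carried over;
#'   `NULL` writes a default header.
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(data, path, reference = NULL) {
  img <- if (is.null(reference)) RNifti::asNifti(data) else {
    ref <- if (is.character(reference)) RNifti::readNifti(reference) else reference
    RNifti::asNifti(data, reference = ref)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an events table (TSV with onset, duration, condition)
#'
#' @param path delimited text file.
#' @return tibble with onset, duration, condition.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "condition")
  if (!all(need %in% names(ev))) {
    il_abort("Events file needs columns onset, duration, condition.",
             "inlimbo_error_io")
  }
  tibble::as_tibble(ev[need])
}

#' Read a pre-built numeric design matrix from TSV
#'
#' @param path delimited text file; columns are regressors, a header row
#'   gives their names.
#' @param tr repetition time in seconds (metadata).
#' @return an `il_design`.
#' @export
read_design_tsv <- function(path, tr = NA_real_) {
  m <- as.matrix(utils::read.delim(path, sep = "\t", check.names = FALSE))
  storage.mode(m) <- "double"
  as_design(m, tr = tr)
}

#' Write the cluster table as TSV
#'
#' Columns: label, size, min_z, max_z, p_cluster, significant and the peak
#' voxel coordinates (0-based).
#'
#' @param clusters an `il_clusters`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, path) {
  tab <- clusters$clusters
  if (nrow(tab)) {
    peaks <- do.call(rbind, tab$peak)
    colnames(peaks) <- paste0("peak_", c("i", "j", "k")[seq_len(ncol(peaks))])
    tab <- cbind(tab[setdiff(names(tab), "peak")], peaks)
  } else {
    tab <- tab[setdiff(names(tab), "peak")]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
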