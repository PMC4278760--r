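# ggplot2 views of 2D maps. Only the first slice is drawn for 3D inputs;
# these plots are meant for the synthetic single-slice studies and quick
# quality control, not publication rendering.

slice_df <- function(arr, dims, value = "value") {
  sl <- if (length(dims) > 2) array(arr, dims)[, , 1] else array(arr, dims)
  d <- dim(sl)
  out <- tibble::tibble(
    i = rep(seq_len(d[1]) - 1L, times = d[2]),
    j = rep(seq_len(d[2]) - 1L, each = d[1]),
    v = as.vector(sl))
  names(out)[3] <- value
  out
}

#' Plot a z-map slice
#'
#' @param object an `il_zmap`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot il_zmap
#' @export
autoplot.il_zmap <- function(object, ...) {
  df <- slice_df(object$z, object$dim, "z")
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "z-map", x = NULL, y = NULL)
}

#' Plot an in-limbo label map
#'
#' Activated regions in orange-red, in-limbo regions in green, and
#' significantly-less regions in grey — the conventional colour scheme for
#' these maps.
#'
#' @param object an `il_limbo`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot il_limbo
#' @export
autoplot.il_limbo <- function(object, ...) {
  lev <- names(limbo_label_codes())
  df <- slice_df(object$labels, object$dim, "code")
  df$label <- factor(lev[df$code + 1L], levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      background = "grey10", less = "grey60",
      in_limbo = "#2e9e43", activated = "#e85d0e")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "in-limbo classification", x = NULL, y = NULL)
}

#' @method autoplot il_run
#' @export
autoplot.il_run <- function(object, ...) autoplot(object$limbo, ...)

#' Volumes across a threshold sweep
#'
#' @param sweep result of [threshold_sweep()].
#' @return a ggplot of activated and in-limbo volume against threshold.
#' @export
plot_sweep <- function(sweep) {
  long <- tidyr_pivot(sweep)
  ggplot2::ggplot(long, ggplot2::aes(.data$z_threshold, .data$volume_cm3,
                                     colour = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cluster-forming z", y = expression(volume ~ (cm^3)))
}

tidyr_pivot <- function(sweep) {
  dplyr::bind_rows(
    tibble::tibble(z_threshold = sweep$z_threshold, class = "activated",
                   volume_cm3 = sweep$vol_activated_cm3),
    tibble::tibble(z_threshold = sweep$z_threshold, class = "in_limbo",
                   volume_cm3 = sweep$vol_in_limbo_cm3))
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
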