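#' Plot an axial slice of a PD map
#'
#' @param object a `svd_pdmap` (or any `svd_volume`).
#' @param slice axial (third-axis) slice index; defaults to the slice with
#'   the highest total PD.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.svd_pdmap <- function(object, slice = NULL, ...) {
  if (is.null(slice))
    slice <- which.max(apply(unclass(object), 3, sum))
  sl <- unclass(object)[, , slice]
  df <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$pd <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$pd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(sl, 1e-9)),
                                  name = "PD") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s probability density, axial slice %d (N = %s)",
                      attr(object, "lesion_class") %||% "lesion", slice,
                      attr(object, "denominator") %||% "?"),
      x = "x (voxel)", y = "y (voxel)") +
    ggplot2::theme_minimal()
}

#' Plot a regional PD table as a heatmap
#'
#' Regions on the vertical axis, lesion classes on the horizontal, tile
#' fill = PD, faceted by laterality.
#' @param object a `svd_region_table`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.svd_region_table <- function(object, ...) {
  classes <- setdiff(names(object), c("region", "laterality"))
  long <- tidyr::pivot_longer(as_tibble(object), dplyr::all_of(classes),
                              names_to = "class", values_to = "pd")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$region,
                                     fill = .data$pd)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$pd)),
                       size = 2.6, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "PD") +
    ggplot2::facet_wrap(~laterality) +
    ggplot2::labs(x = "lesion class", y = NULL) +
    ggplot2::theme_minimal()
}
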