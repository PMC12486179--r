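# ggplot2 views of the pipeline's result types.

#' Plot an axial slice of a volume, mask or label volume
#'
#' @param vol a [voxel_volume()] (grayscale), [binary_mask()] or
#'   [label_volume()].
#' @param z slice index (default: middle slice).
#' @param overlay optional [label_volume()] drawn over a grayscale slice.
#' @return a ggplot.
#' @export
plot_slice <- function(vol, z = NULL, overlay = NULL) {
  d <- dim(vol$values)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- vol$values[, , z]
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(sl)
  df$x_mm <- vol$origin[1] + (df$x - 1) * vol$spacing[1]
  df$y_mm <- vol$origin[2] + (df$y - 1) * vol$spacing[2]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm))
  if (inherits(vol, "label_volume")) {
    df$label <- factor(ifelse(df$value == 0, NA, df$value))
    p <- p + ggplot2::geom_raster(data = df[!is.na(df$label), ],
                                  ggplot2::aes(fill = .data$label))
  } else {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white")
  }
  if (!is.null(overlay)) {
    ov <- overlay$values[, , z]
    df$ov <- as.vector(ov)
    p <- p + ggplot2::geom_raster(
      data = df[df$ov > 0, ],
      ggplot2::aes(fill = NULL, alpha = 0.5),
      fill = "red", show.legend = FALSE)
  }
  p + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("slice z = %d", z)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' p-value overview of a comparison table
#'
#' @param object a `cysthead_table` from [build_table()].
#' @param alpha significance line.
#' @param ... unused.
#' @return a ggplot of -log10(p) per variable.
#' @export
autoplot.cysthead_table <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$variable, .data$p),
                                   y = -log10(.data$p),
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  fill = sprintf("p < %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' Microarchitecture panel comparison plot
#'
#' @param object a tibble of per-ROI panels ([microarch_panel()] rows,
#'   optionally with a `group` column).
#' @param ... unused.
#' @return a faceted ggplot of the 8 parameters.
#' @export
plot_microarch <- function(object, ...) {
  pars <- intersect(c("bv_tv", "bs_bv", "tb_th_um", "tb_sp_um", "tb_n_mm",
                      "smi", "da", "conn_d_mm3"), names(object))
  long <- tidyr::pivot_longer(object, dplyr::all_of(pars),
                              names_to = "parameter", values_to = "value")
  aes <- if ("group" %in% names(object))
    ggplot2::aes(x = .data$group, y = .data$value)
  else ggplot2::aes(x = "", y = .data$value)
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
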