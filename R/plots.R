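#' Volcano plot of an enrichment fit
#'
#' Log2 fold change against -log10 p-value, with the classification
#' cutoffs drawn as reference lines.
#'
#' @param object A `ps_enrichment` object.
#' @param fc_cutoff,p_cutoff Cutoffs to draw (defaults match
#'   [classify_ps_enriched()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ps_enrichment
#' @export
autoplot.ps_enrichment <- function(object, fc_cutoff = 2, p_cutoff = 0.05,
                                   ...) {
  df <- tidy(object)
  df$called <- 2^df$log2fc > fc_cutoff & df$p_value < p_cutoff
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                   colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = log2(fc_cutoff), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "Ps-enriched") +
    ggplot2::labs(x = "log2(Ps/CB)", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Render a cell image with its masks
#'
#' @param object A [cell_image()].
#' @param ... Unused.
#' @return A ggplot object: intensity raster with cell and nuclear mask
#'   boundaries.
#' @method autoplot cell_image
#' @export
autoplot.cell_image <- function(object, ...) {
  h <- nrow(object$raster)
  w <- ncol(object$raster)
  df <- tibble::tibble(
    row = rep(seq_len(h) - 1, times = w),
    col = rep(seq_len(w) - 1, each = h),
    intensity = as.vector(object$raster),
    cell = as.vector(object$cell_mask) * 1,
    nuc = as.vector(object$nuc_mask) * 1
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$cell), breaks = 0.5,
                          colour = "white", linewidth = 0.3) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$nuc), breaks = 0.5,
                          colour = "cyan", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = object$label) +
    ggplot2::theme_void()
}

#' Cumulative-fraction plot
#'
#' Plots empirical cumulative fractions of a value (for example the
#' per-gene change in log2 enrichment) for one or more groups of genes.
#'
#' @param data Data frame.
#' @param value Column of values (tidy-eval).
#' @param group Optional grouping column (tidy-eval).
#' @return A ggplot object.
#' @export
plot_cumulative_fraction <- function(data, value, group = NULL) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  if (rlang::quo_is_null(group)) {
    df <- cumulative_fraction(dplyr::pull(data, !!value))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$fraction))
  } else {
    df <- data |>
      dplyr::group_by(!!group) |>
      dplyr::reframe(cumulative_fraction(!!value)) |>
      dplyr::rename(group = !!group)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$fraction,
                                          colour = factor(.data$group)))
  }
  p + ggplot2::geom_step() +
    ggplot2::labs(x = "value", y = "cumulative fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Strip plot of per-cell PDI values
#'
#' Shows every individual PDI value per channel/group (the convention for
#' depicting population variability), with the group mean overlaid and
#' the diffuse reference PDI = 1 marked.
#'
#' @param data A table from [pdi_batch()] (or any data frame with `pdi`).
#' @param group Grouping column (tidy-eval), default `label`.
#' @return A ggplot object.
#' @export
plot_pdi <- function(data, group = label) {
  group <- rlang::enquo(group)
  ggplot2::ggplot(data, ggplot2::aes(factor(!!group), .data$pdi)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "PDI") +
    ggplot2::theme_minimal()
}
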