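# ggplot2 graphics for the main result types.

#' Histogram of per-fiber linear synapse densities
#'
#' Frequency distribution of linear densities for one fiber class, the
#' standard way to show how unevenly synapses are spread over individual
#' dendrites or axons.
#'
#' @param records Output of [linear_synapse_density()].
#' @param fiber_class Class to plot.
#' @param binwidth Bin width in synapses/um.
#' @return A ggplot object.
#' @export
plot_linear_density_histogram <- function(records,
                                          fiber_class = "spiny_dendrite",
                                          binwidth = 0.25) {
  df <- records[records$fiber_class == fiber_class & records$included, ,
                drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density_total)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "#33658A", color = "white") +
    ggplot2::labs(x = "linear synapse density (synapses/µm of shaft)",
                  y = "number of fibers", title = fiber_class) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.length_report <- function(object, ...) {
  df <- object$by_class
  df$fiber_class <- factor(df$fiber_class,
                           levels = df$fiber_class[order(-df$length_m_per_mm3)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fiber_class,
                                   y = .data$length_m_per_mm3)) +
    ggplot2::geom_col(fill = "#86BBD8") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "fiber length (m/mm³)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @export
autoplot.target_distribution <- function(object, ...) {
  df <- object$fourway
  df$category <- factor(df$category, levels = df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$pct)) +
    ggplot2::geom_col(fill = c("#2F7A3D", "#8FCB9B", "#B23A48", "#E8A49C")) +
    ggplot2::labs(x = NULL, y = "% of synapses") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.region_report <- function(object, ...) {
  autoplot(object$lengths) +
    ggplot2::ggtitle(sprintf("%s: %.2f synapses/µm³, %.2f m/mm³",
                             object$region,
                             object$density$density_per_um3[3],
                             object$lengths$total_m_per_mm3))
}
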