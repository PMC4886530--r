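# ggplot2 displays for the main result types.

#' @method autoplot pcoa_ordination
#' @export
autoplot.pcoa_ordination <- function(object, colour = "quality",
                                     shape = "batch", ...) {
  g <- glance(object)
  sc <- object$scores
  aes_args <- list(x = rlang::sym("Axis1"))
  aes_args$y <- if ("Axis2" %in% names(sc)) rlang::sym("Axis2") else NULL
  if (!is.null(colour) && colour %in% names(sc)) {
    aes_args$colour <- rlang::sym(colour)
  }
  if (!is.null(shape) && shape %in% names(sc)) {
    aes_args$shape <- rlang::sym(shape)
  }
  ggplot2::ggplot(sc, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PCoA1 (%.1f%%)", 100 * g$var_explained_axis1),
      y = if (is.na(g$var_explained_axis2)) "PCoA2"
      else sprintf("PCoA2 (%.1f%%)", 100 * g$var_explained_axis2)
    ) +
    ggplot2::theme_minimal()
}

#' Genus abundance trajectories over the fermentation course
#'
#' One line per batch, coloured by final quality; shows how the plotted
#' genus (Lactobacillus by default) diverges between good and spoiled
#' batches around day 7.
#'
#' @param cohort Wide genus table with `batch`, `day`, `quality` metadata.
#' @param genus Genus column to plot.
#' @return A ggplot object.
#' @export
plot_genus_trajectories <- function(cohort, genus = "Lactobacillus") {
  if (!genus %in% names(cohort)) abort(sprintf("genus `%s` not found", genus))
  ggplot2::ggplot(cohort, ggplot2::aes(
    x = .data$day, y = .data[[genus]],
    group = .data$batch, colour = .data$quality
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::labs(y = paste(genus, "relative abundance"), x = "day") +
    ggplot2::theme_minimal()
}

#' Heatmap of genus-genus Spearman correlations
#'
#' @param rho Correlation matrix from [spearman_antagonism()].
#' @return A ggplot object.
#' @export
plot_antagonism <- function(rho) {
  long <- as_tibble(as.table(rho), .name_repair = "minimal")
  names(long) <- c("genus_a", "genus_b", "rho")
  ggplot2::ggplot(long, ggplot2::aes(.data$genus_a, .data$genus_b,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5),
                   axis.title = ggplot2::element_blank())
}

#' Functional gene counts and abundance per sample
#'
#' @param summary_tbl Output of [functional_summary()].
#' @param value `"total_abundance"` (default) or `"n_genes"`.
#' @return A ggplot object.
#' @export
plot_functional_summary <- function(summary_tbl, value = "total_abundance") {
  ggplot2::ggplot(summary_tbl, ggplot2::aes(
    x = .data$sample_id, y = .data[[value]], fill = .data$label
  )) +
    ggplot2::geom_col() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
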