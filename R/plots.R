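#' Plot a population call on its t-SNE layout
#'
#' @param object a `population_call` tibble from [call_populations()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot population_call
#' @export
autoplot.population_call <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       colour = factor(.data$population))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "Population",
                  caption = sprintf("KL divergence of chosen run: %.3f",
                                    attr(object, "kl"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the spike-in technical-noise fit
#'
#' CV^2 versus mean on log-log axes with the fitted a1/mu + alpha0 curve.
#'
#' @param fit a `technoise_fit`.
#' @param hvg optional `hvg_selection` to overlay the endogenous genes,
#'   coloured by selection.
#' @return a ggplot.
#' @export
plot_technoise <- function(fit, hvg = NULL) {
  p <- ggplot2::ggplot(fit$points, ggplot2::aes(.data$mu, .data$cv2))
  if (!is.null(hvg))
    p <- p + ggplot2::geom_point(
      data = hvg$ranking,
      ggplot2::aes(colour = .data$selected), size = 0.6, alpha = 0.6)
  grid <- tibble::tibble(mu = exp(seq(log(min(fit$points$mu)),
                                      log(max(fit$points$mu)),
                                      length.out = 200)))
  grid$cv2 <- predict(fit, grid$mu)
  p +
    ggplot2::geom_point(shape = 21, fill = "gold", size = 2) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean count", y = expression(CV^2),
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' Dot plot of gene-set over-representation results
#'
#' @param ora tibble from [ora_hypergeometric()].
#' @param max_sets show at most this many top sets.
#' @return a ggplot.
#' @export
plot_enrichment <- function(ora, max_sets = 20) {
  d <- dplyr::slice_min(dplyr::filter(ora, !is.na(.data$p_value)),
                        .data$p_value, n = max_sets, with_ties = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(.data$gene_ratio,
                                  stats::reorder(.data$set, .data$gene_ratio),
                                  size = .data$overlap,
                                  colour = -log10(.data$p_adj))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "gene ratio", y = NULL, size = "overlap",
                  colour = expression(-log[10]~FDR)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a gene-level correlation panel
#'
#' @param panel output of [correlation_panel()].
#' @return a ggplot of the gene-gene Pearson correlations, genes grouped
#'   by profile.
#' @export
plot_correlation_panel <- function(panel) {
  m <- panel$gene_panel
  map <- attr(m, "profile")
  d <- tidyr::expand_grid(gene_a = map$gene, gene_b = map$gene)
  d$r <- as.numeric(m[cbind(match(d$gene_a, rownames(m)),
                            match(d$gene_b, colnames(m)))])
  d$gene_a <- factor(d$gene_a, levels = map$gene)
  d$gene_b <- factor(d$gene_b, levels = map$gene)
  ggplot2::ggplot(d, ggplot2::aes(.data$gene_a, .data$gene_b,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
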