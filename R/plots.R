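#' Plot a neutral-model fit
#'
#' Occurrence frequency against log10 mean relative abundance, with the
#' fitted neutral expectation (solid) and its 95% Wilson band (dashed);
#' points coloured by partition.
#'
#' @param object a `neutral_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.neutral_fit <- function(object, ...) {
  d <- dplyr::arrange(object$otus, .data$mean_relabund)
  ggplot2::ggplot(d, ggplot2::aes(log10(.data$mean_relabund))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$freq_observed,
                                     colour = .data$partition),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$freq_predicted)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_lower), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_upper), linetype = "dashed") +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "occurrence frequency",
                  subtitle = sprintf("m = %.3f, R² = %.3f", object$m, object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot assembly-process fractions
#'
#' Single stacked bar of the five-process percentages.
#'
#' @param object an `assembly_result`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.assembly_result <- function(object, ...) {
  d <- dplyr::mutate(object$fractions,
                     process = factor(.data$process, levels = rev(process_levels)))
  ggplot2::ggplot(d, ggplot2::aes(x = "all pairs", y = .data$percent,
                                  fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of sample pairs", fill = "process") +
    ggplot2::theme_minimal()
}

#' Plot a co-occurrence network
#'
#' Fruchterman-Reingold layout with positive edges in one colour and
#' negative in another; node size scales with degree.
#'
#' @param object a `cooccur_network`
#' @param seed layout seed
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.cooccur_network <- function(object, seed = 1L, ...) {
  g <- object$graph
  if (igraph::vcount(g) == 0) stop("empty network", call. = FALSE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- new_tbl(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                   degree = igraph::degree(g))
  el <- igraph::as_edgelist(g)
  edges <- new_tbl(x = nodes$x[match(el[, 1], nodes$name)],
                   y = nodes$y[match(el[, 1], nodes$name)],
                   xend = nodes$x[match(el[, 2], nodes$name)],
                   yend = nodes$y[match(el[, 2], nodes$name)],
                   sign = igraph::E(g)$sign)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$sign),
                          alpha = 0.5, linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, size = .data$degree),
                        alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(0.5, 3)) +
    ggplot2::theme_void()
}

#' Ordination scatter plot of PCoA coordinates
#'
#' @param ord result of [pcoa_ord()]
#' @param groups optional group label per sample (in the same order)
#' @return a ggplot
#' @export
plot_pcoa <- function(ord, groups = NULL) {
  d <- ord$points
  if (!is.null(groups)) d$group <- groups
  pr <- 100 * ord$proportion
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(x = sprintf("PCoA1 (%.1f%%)", pr[1]),
                  y = sprintf("PCoA2 (%.1f%%)", pr[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}
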