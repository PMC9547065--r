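#' Plot a super-enhancer rank curve
#'
#' The classic hockey-stick: scaled rank against scaled net H3K27Ac
#' signal, with the elbow cutoff marked and SEs highlighted.
#'
#' @param object An `se_call` from [rose_cutoff()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot se_call
#' @export
autoplot.se_call <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$is_SE)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = d$x[d$rank == attr(object, "cutoff_index")],
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "scaled rank", y = "scaled net H3K27Ac signal",
                  colour = "super-enhancer",
                  title = sprintf("%d super-enhancers of %d stitched regions",
                                  sum(d$is_SE), nrow(d)))
}

#' Plot an insulation track
#'
#' Per-bin log2 insulation along the chromosome; optional TAD boundaries
#' overlaid as vertical lines.
#'
#' @param object An `insulation_track` from [diamond_insulation()].
#' @param boundaries Optional tibble of boundary positions (`chrom`,
#'   `pos`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot insulation_track
#' @export
autoplot.insulation_track <- function(object, boundaries = NULL, ...) {
  d <- as_tibble(object)[as_tibble(object)$valid, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                       y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "log2 insulation score")
  if (!is.null(boundaries)) {
    p <- p + ggplot2::geom_vline(data = boundaries,
                                 ggplot2::aes(xintercept = .data$pos),
                                 colour = "steelblue", alpha = 0.5,
                                 linetype = "dotted")
  }
  p
}

#' Plot an enrichment result
#'
#' Histogram of the random-set statistic with the observed value marked.
#'
#' @param object An `enrichment_result` from [enrichment_t()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- tibble(value = object$random_values)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = object$statistic, y = "random sets",
                  title = sprintf("t(%d) = %.2f, p = %.3g [%s]",
                                  object$df, object$t, object$p,
                                  object$direction))
}

#' Boxplot of loop sizes by group
#'
#' @param loops Loop table.
#' @param groups Character vector (one per loop) assigning each loop to a
#'   group (e.g. compartment combination).
#' @return A ggplot object.
#' @export
plot_loop_sizes <- function(loops, groups) {
  d <- tibble(size = loop_sizes(loops), group = groups)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$size)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "loop size (bp)")
}
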