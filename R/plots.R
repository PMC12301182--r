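#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stringency sweep: neighbor percentage vs co-acquisition count
#'
#' Observed percent of neighboring co-acquisitions (solid, points) and the
#' null expectation (dashed) against the number of co-acquisitions, the
#' comparability axis across methods. Excluded levels (< 20 pairs) are drawn
#' hollow.
#'
#' @param object An `hgt_eval` tibble from [stringency_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hgt_eval
#' @export
autoplot.hgt_eval <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_coacquisitions,
                                   colour = .data$method)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pct_neighbors)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$pct_neighbors,
                                     shape = .data$excluded), size = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected_pct_neighbors),
                       linetype = "dashed") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "co-acquisitions (log scale)",
                  y = "% neighboring co-acquisitions",
                  shape = "excluded (<20 pairs)") +
    ggplot2::theme_minimal()
}

#' Plot a typicality rank curve with its smoothed fit
#'
#' @param object A `typicality_table` from [typicality_scores()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot typicality_table
#' @export
autoplot.typicality_table <- function(object, ...) {
  df <- tibble::tibble(rank = seq_along(object$curve),
                       score = object$curve,
                       smoothed = object$smoothed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$score),
                        size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "red") +
    ggplot2::labs(x = "gene rank (ascending typicality)",
                  y = "typicality score") +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise method distances (1 - max Overlap Coefficient)
#'
#' @param object An `hgt_dist` matrix from [build_distance_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hgt_dist
#' @export
autoplot.hgt_dist <- function(object, ...) {
  nm <- rownames(object)
  df <- tidyr::expand_grid(method_a = nm, method_b = nm)
  df$distance <- mapply(function(a, b) object[a, b], df$method_a, df$method_b)
  ggplot2::ggplot(df, ggplot2::aes(.data$method_a, .data$method_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - maxOC") +
    ggplot2::theme_minimal()
}
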