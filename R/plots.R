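#' Plot insertion sites along the genome
#'
#' Lollipop-style overview: one segment per site at its genomic position,
#' height equal to the supporting read count, faceted by chromosome.
#'
#' @param object An insertion-site table from [cluster_breakpoints()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot insertion_sites
#' @export
autoplot.insertion_sites <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$read_count)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          linewidth = 0.6) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "genomic position (bp)",
                  y = "supporting reads",
                  title = "Insertion sites") +
    ggplot2::theme_minimal()
}

#' Plot a zero-inflated Poisson fit against the observed counts
#'
#' Observed window-count frequencies with the fitted ZIP probability mass
#' overlaid.
#'
#' @param object A `zip_fit` object.
#' @param max_k Largest count to display (default: 99.9th percentile).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zip_fit
#' @export
autoplot.zip_fit <- function(object, max_k = NULL, ...) {
  counts <- object$counts
  if (is.null(max_k))
    max_k <- max(3, stats::quantile(counts, 0.999))
  k <- 0:ceiling(max_k)
  obs <- vapply(k, function(x) mean(counts == x), double(1))
  fit <- zip_dens(k, object$pi, object$lambda)
  df <- tibble(k = rep(k, 2),
               prob = c(obs, fit),
               which = rep(c("observed", "fitted"),
                           each = length(obs)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$prob,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "window read count", y = "probability",
                  fill = NULL,
                  title = sprintf("ZIP fit: pi = %.3f, lambda = %.3f",
                                  object$pi, object$lambda)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
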