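# ggplot2 views of the main result tables.

#' Bar plot of topology-type counts
#'
#' @param topology Tibble from [classify_topology()] (optionally with a
#'   `dataset` column).
#' @return A ggplot object.
#' @export
plot_topology <- function(topology) {
  d <- topology %>% filter(!is.na(.data$type)) %>%
    mutate(type = factor(.data$type, levels = 1:5))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$type)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "topology type", y = "cis-NATs") +
    ggplot2::theme_minimal()
  if ("dataset" %in% names(d)) p <- p + ggplot2::facet_wrap(~dataset)
  p
}

#' Scale vs significance plot of per-interval conservation tests
#'
#' @param lrt_tbl Tibble from [scale_lrt_table()].
#' @param alpha Significance threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_conservation <- function(lrt_tbl, alpha = 0.05) {
  d <- lrt_tbl %>% filter(!.data$untestable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scale, y = -log10(.data$p_value),
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "branch-length scale (log)", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Null-distribution histogram with the observed statistic
#'
#' @param null_res Null-stage result (`mean`, `sd`, `values`, `observed`)
#'   as produced by [run_pipeline()], or a list with those elements.
#' @return A ggplot object.
#' @export
plot_null <- function(null_res) {
  d <- tibble(value = null_res$values)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = null_res$observed, colour = "firebrick") +
    ggplot2::labs(x = "statistic under matched resampling", y = "replicates") +
    ggplot2::theme_minimal()
}
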