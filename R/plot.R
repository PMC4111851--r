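# ggplot2 views of the main result types.

#' Plot corrected read depth along the genome
#'
#' @param object A `window_set` with counts (and, when available,
#'   corrected depth).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot window_set
autoplot.window_set <- function(object, ...) {
  df <- as_tibble(object)
  y <- if (all(is.na(df$rd_corrected))) "read_count" else "rd_corrected"
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data[[y]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = if (y == "read_count") "read count" else "corrected depth",
                  title = sprintf("%s windows (%s dialect)",
                                  attr(object, "kind"), attr(object, "dialect"))) +
    ggplot2::theme_minimal()
}

#' Plot CNV calls as genomic segments
#'
#' @param object A `cnv_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot cnv_calls
autoplot.cnv_calls <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$individual,
                                   yend = .data$individual,
                                   colour = .data$state)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution with the observed value
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot enrichment_result
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null), ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = object$statistic, y = "replicates",
                  title = sprintf("fold = %.2f, p = %.3g", object$fold,
                                  object$p)) +
    ggplot2::theme_minimal()
}

#' Plot a copy-number profile
#'
#' @param object A `cn_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot cn_profile
autoplot.cn_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$cn)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 2, linetype = 2) +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "copy number") +
    ggplot2::theme_minimal()
}
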