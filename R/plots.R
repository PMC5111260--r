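# ggplot2 displays for the main result types.

#' @describeIn connectedness_null-plots Null histograms with the observed
#'   connectedness as a dotted line, faceted by stratum.
#' @export
autoplot.connectedness_null <- function(object, ...) {
  nulls <- dplyr::bind_rows(lapply(names(object$nulls), function(key) {
    tibble::tibble(stratum = key, connectedness = object$nulls[[key]])
  }))
  nulls$stratum <- factor(nulls$stratum, levels = names(object$nulls))
  obs <- object$summary
  obs$stratum <- factor(obs$stratum, levels = names(object$nulls))
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$connectedness)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        linetype = "dotted", colour = "red") +
    ggplot2::facet_wrap(~stratum, scales = "free") +
    ggplot2::labs(x = "network connectedness (edges)", y = "null frequency")
}

#' Plots for connectedness-null results
#'
#' @param object,result A `connectedness_null`.
#' @param ... Ignored.
#' @name connectedness_null-plots
NULL

#' @describeIn connectedness_null-plots Adjusted significance per stratum as
#'   -log10(q), grouped by region and stage.
#' @export
plot_connectedness_significance <- function(result) {
  stopifnot(inherits(result, "connectedness_null"),
            "q" %in% names(result$summary))
  df <- result$summary
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$stage), y = -log10(.data$q),
                                   fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = -log10(result$alpha %||% 0.05),
                        linetype = "dashed") +
    ggplot2::labs(x = "developmental stage", y = "-log10(adjusted p)")
}

#' Significance along a chromosome with interaction regions highlighted
#'
#' Manhattan-style scatter of per-gene -log10(p) by genomic position, with
#' optional shaded high-interaction intervals.
#'
#' @param deg_table Per-gene table with `chrom`, `start`, `p`.
#' @param chrom Chromosome to draw.
#' @param intervals Optional interval tibble (`chrom`, `start`, `end`).
#' @return A ggplot object.
#' @export
plot_chromosome_pvalues <- function(deg_table, chrom, intervals = NULL) {
  df <- deg_table[deg_table$chrom == chrom, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6,
                                        y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom), y = "-log10(p)")
  if (!is.null(intervals)) {
    iv <- intervals[intervals$chrom == chrom, ]
    if (nrow(iv)) {
      p <- p + ggplot2::geom_rect(
        data = iv,
        ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
        ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.3,
        inherit.aes = FALSE
      )
    }
  }
  p
}

#' Degree distribution of a network on log-log axes
#'
#' @param network A `coexpression_network`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  d <- network$degree[network$degree > 0]
  tab <- table(d)
  df <- tibble::tibble(degree = as.numeric(names(tab)),
                       frequency = as.numeric(tab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "frequency")
}
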