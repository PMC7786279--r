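#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a consensus clustering into sample-level rows
#' @param x A `consensus_clustering` object.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `class`.
#' @exportS3Method generics::tidy
tidy.consensus_clustering <- function(x, ...) {
  tibble::tibble(sample = names(x$labels),
                 class = sprintf("Class%d", unname(x$labels)))
}

#' One-row stability summary of a consensus clustering
#' @param x A `consensus_clustering` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.consensus_clustering <- function(x, ...) {
  tibble::tibble(rank = x$rank, cophenetic = x$cophenetic,
                 silhouette = x$silhouette,
                 n_classes_found = x$n_classes_found, n_runs = x$n_runs)
}

#' Heatmap of a consensus matrix
#' @param object A `consensus_clustering` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.consensus_clustering <- function(object, ...) {
  C <- object$consensus_matrix
  ord <- stats::hclust(stats::as.dist(1 - C), method = "average")$order
  df <- tidyr::expand_grid(i = seq_len(nrow(C)), j = seq_len(ncol(C)))
  df$consensus <- C[ord, ord][cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                   fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix, rank %d",
                                  object$rank)) +
    ggplot2::theme_minimal()
}

#' One-row summary of a log-rank test
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.logrank_test <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = x$df,
                 p_value = x$p_value)
}

#' One-row summary of a moderated-t table
#' @param x A `deg_table`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.deg_table <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 prior_df = attr(x, "prior_df"),
                 prior_var = attr(x, "prior_var"),
                 n_p05 = sum(x$p <= 0.05),
                 n_fdr05 = sum(x$p_adj <= 0.05))
}

#' Volcano plot of a moderated-t table
#' @param object A `deg_table`.
#' @param lfc_min,p_max Thresholds drawn as guides (defaults 1 / 0.05).
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.deg_table <- function(object, lfc_min = 1, p_max = 0.05, ...) {
  df <- tibble::tibble(lfc = object$log2_fc,
                       nlp = -log10(pmax(object$p, 1e-300)),
                       hit = abs(object$log2_fc) >= lfc_min &
                         object$p <= p_max)
  ggplot2::ggplot(df, ggplot2::aes(.data$lfc, .data$nlp,
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Bar chart of TF-knockout growth ratios
#' @param object A `tf_screen` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.tf_screen <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      tf = stats::reorder(.data$tf, .data$growth_ratio))
  ggplot2::ggplot(df, ggplot2::aes(.data$tf, .data$growth_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "growth ratio (knockout / wildtype)") +
    ggplot2::theme_minimal()
}
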