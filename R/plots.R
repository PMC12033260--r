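#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot integrative steroid scores
#'
#' Ranked bar chart of the overall per-steroid score, the standard way to
#' display which steroid carries the strongest combined concentration +
#' expression signal.
#'
#' @param object A `steroid_scores` tibble from [steroid_overall_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot steroid_scores
#' @export
autoplot.steroid_scores <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$steroid <- stats::reorder(df$steroid, df$overall_score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$steroid,
                                   y = .data$overall_score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "overall steroid score (mean layer z-score)") +
    ggplot2::theme_minimal()
}

#' Plot a receptor / immune-fraction correlation screen
#'
#' Heatmap of Pearson r per (receptor gene, immune population), with
#' significant (adjusted p < alpha) cells marked.
#'
#' @param object A `receptor_screen` tibble from [receptor_immune_screen()].
#' @param alpha Significance threshold on the adjusted p-value.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot receptor_screen
#' @export
autoplot.receptor_screen <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$sig <- ifelse(df$p_adjusted < alpha, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population, y = .data$gene,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig), size = 3) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-cell module scores by group
#'
#' Violin + box plot of gene-set module scores split by cell group (e.g.
#' tumour vs blood immune cells).
#'
#' @param object A `module_scores` tibble from [module_score()].
#' @param group Per-cell group labels (defaults to a `group` column if the
#'   tibble carries one).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot module_scores
#' @export
autoplot.module_scores <- function(object, group = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (is.null(group)) {
    if (!"group" %in% names(df)) {
      stop("supply group labels or a 'group' column", call. = FALSE)
    }
    group <- df$group
  }
  df$group <- group
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score,
                                   fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::labs(x = NULL,
                  y = paste0(attr(object, "set_name") %||% "module",
                             " score"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
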