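#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation over pairwise-complete observations, with the
#' usual two-sided test based on `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom (perfect correlations get the limiting p of 0).
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value in
#'   either are dropped.
#' @return A one-row tibble with `r`, `p_value` and `n` (pairs used).
#' @export
cor_pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop("need at least 3 complete pairs for a correlation test", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Benjamini–Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value family, capped at 1
#' and returned in the input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Screen steroid receptor genes against immune-population fractions
#'
#' For every (receptor gene, immune population) pair, computes the Pearson
#' correlation between the gene's bulk expression and the deconvolved
#' population fraction across the samples shared by the two matrices, with
#' two-sided p-values and Benjamini–Hochberg adjustment. This is the screen
#' that exposes, e.g., the inverse association of glucocorticoid / androgen /
#' progestogen receptor expression with activated dendritic cells and M1
#' macrophages, and the positive association with M2 macrophages and resting
#' mast cells.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param fractions Samples-by-populations fraction matrix (values in
#'   \[0, 1\], e.g. LM22-style deconvolution output).
#' @param genes Receptor gene symbols to screen (matched case-insensitively).
#' @param adjust `"table"` (default): one BH family across all pairs;
#'   `"per_gene"`: adjust within each gene.
#' @return A tibble of class `receptor_screen`, one row per (gene,
#'   population), with `gene`, `population`, `r`, `n`, `p_value`,
#'   `p_adjusted`. Genes absent from `expr` are dropped and reported in the
#'   `"missing_genes"` attribute (and as a message).
#' @export
receptor_immune_screen <- function(expr, fractions, genes,
                                   adjust = c("table", "per_gene")) {
  adjust <- match.arg(adjust)
  stopifnot(is.matrix(expr), is.matrix(fractions))
  if (any(fractions < 0 | fractions > 1, na.rm = TRUE)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  shared <- intersect(colnames(expr), rownames(fractions))
  if (length(shared) < 3L) {
    stop("need at least 3 samples shared between expression and fractions",
         call. = FALSE)
  }
  idx <- match(norm_gene(genes), norm_gene(rownames(expr)))
  missing_genes <- genes[is.na(idx)]
  if (length(missing_genes)) {
    rlang::inform(paste0("genes not found in expression matrix: ",
                         paste(missing_genes, collapse = ", ")))
  }
  genes_found <- rownames(expr)[idx[!is.na(idx)]]
  if (length(genes_found) == 0L) {
    stop("none of the requested genes are present in the expression matrix",
         call. = FALSE)
  }
  # deterministic sample order regardless of input column order
  shared <- sort(shared)
  e <- expr[genes_found, shared, drop = FALSE]
  f <- fractions[shared, , drop = FALSE]

  out <- tidyr::expand_grid(gene = genes_found,
                            population = colnames(fractions)) |>
    dplyr::mutate(purrr::map2_dfr(.data$gene, .data$population,
                                  function(g, p) {
                                    cor_pearson(e[g, ], f[, p])
                                  })) |>
    dplyr::rename(n_samples = "n")

  # perfect correlations carry the limiting p of 0; clamp to the smallest
  # representable double so the table keeps p in (0, 1] for BH
  out$p_value <- pmax(out$p_value, .Machine$double.xmin)
  out$p_adjusted <- if (adjust == "table") {
    bh_adjust(out$p_value)
  } else {
    stats::ave(out$p_value, out$gene, FUN = bh_adjust)
  }
  attr(out, "missing_genes") <- missing_genes
  class(out) <- c("receptor_screen", class(out))
  out
}
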