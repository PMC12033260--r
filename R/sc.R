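#' Single-cell QC thresholds
#'
#' Cell-level quality bounds on detected genes, total UMIs and mitochondrial
#' percentage. Two named dialects are provided, matching thresholds commonly
#' used for in-house 10x data and for the public TNBC tumour/blood atlas:
#' * `"inhouse"` — keep cells with **more than** 200 and **fewer than** 7,500
#'   detected genes, a UMI count **below** 60,000, and at most 20%
#'   mitochondrial counts (cells above 20% are discarded);
#' * `"zhang"` — exclude cells with fewer than 400 or more than 8,000 genes,
#'   a UMI count below 600 or above 120,000, or more than 10% mitochondrial
#'   counts.
#'
#' Strict vs inclusive bounds follow the wording of each rule; custom bounds
#' can be supplied directly.
#'
#' @param dialect `"inhouse"` or `"zhang"`; ignored when explicit bounds are
#'   given.
#' @param min_genes,max_genes,min_umi,max_umi,max_pct_mito Numeric bounds on
#'   the kept cells.
#' @param inclusive Named logical vector: is each *keep*-side comparison
#'   inclusive? Names `genes_lo`, `genes_hi`, `umi_lo`, `umi_hi`, `mito`.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(dialect = c("inhouse", "zhang"),
                          min_genes = NULL, max_genes = NULL,
                          min_umi = NULL, max_umi = NULL,
                          max_pct_mito = NULL, inclusive = NULL) {
  if (is.null(min_genes)) {
    dialect <- match.arg(dialect)
    th <- switch(dialect,
      inhouse = list(min_genes = 200, max_genes = 7500,
                     min_umi = -Inf, max_umi = 60000, max_pct_mito = 20,
                     inclusive = c(genes_lo = FALSE, genes_hi = FALSE,
                                   umi_lo = TRUE, umi_hi = FALSE,
                                   mito = TRUE)),
      zhang = list(min_genes = 400, max_genes = 8000,
                   min_umi = 600, max_umi = 120000, max_pct_mito = 10,
                   inclusive = c(genes_lo = TRUE, genes_hi = TRUE,
                                 umi_lo = TRUE, umi_hi = TRUE, mito = TRUE))
    )
    th$dialect <- dialect
  } else {
    if (is.null(inclusive)) {
      inclusive <- c(genes_lo = TRUE, genes_hi = TRUE, umi_lo = TRUE,
                     umi_hi = TRUE, mito = TRUE)
    }
    th <- list(min_genes = min_genes, max_genes = max_genes,
               min_umi = min_umi %||% -Inf, max_umi = max_umi %||% Inf,
               max_pct_mito = max_pct_mito %||% 100,
               inclusive = inclusive, dialect = "custom")
  }
  if (th$min_genes >= th$max_genes || th$min_umi >= th$max_umi) {
    stop("QC lower bounds must be below upper bounds", call. = FALSE)
  }
  if (th$max_pct_mito < 0 || th$max_pct_mito > 100) {
    stop("max_pct_mito must lie in [0, 100]", call. = FALSE)
  }
  structure(th, class = "qc_thresholds")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cmp_keep <- function(x, bound, inclusive, side) {
  if (side == "lo") {
    if (inclusive) x >= bound else x > bound
  } else {
    if (inclusive) x <= bound else x < bound
  }
}

#' Filter cells on QC covariates
#'
#' Keeps the cells whose detected-gene count, UMI count and mitochondrial
#' percentage all satisfy the thresholds, and reports how many cells each
#' criterion removed (individually and jointly).
#'
#' @param cells A [cell_matrix()].
#' @param thresholds A [qc_thresholds()] object (default: the in-house
#'   dialect).
#' @return A list of class `qc_result` with `cells` (the filtered
#'   [cell_matrix()]) and `report` (tibble of per-criterion removal counts).
#' @export
qc_filter <- function(cells, thresholds = qc_thresholds("inhouse")) {
  stopifnot(inherits(cells, "cell_matrix"),
            inherits(thresholds, "qc_thresholds"))
  m <- cells$meta
  inc <- thresholds$inclusive
  pass <- tibble::tibble(
    genes_low = cmp_keep(m$n_genes, thresholds$min_genes, inc[["genes_lo"]], "lo"),
    genes_high = cmp_keep(m$n_genes, thresholds$max_genes, inc[["genes_hi"]], "hi"),
    umi_low = cmp_keep(m$n_umi, thresholds$min_umi, inc[["umi_lo"]], "lo"),
    umi_high = cmp_keep(m$n_umi, thresholds$max_umi, inc[["umi_hi"]], "hi"),
    mito = cmp_keep(m$pct_mito, thresholds$max_pct_mito, inc[["mito"]], "hi")
  )
  keep <- Reduce(`&`, pass) %||% logical(0)
  if (nrow(m) == 0L) keep <- logical(0)
  report <- tibble::tibble(
    criterion = c(names(pass), "any"),
    n_removed = unname(c(vapply(pass, function(p) sum(!p), integer(1)),
                         sum(!keep))),
    n_total = nrow(m)
  )
  kept <- cell_matrix(
    cells$counts[, keep, drop = FALSE],
    group = if ("group" %in% names(m)) m$group[keep] else NULL,
    mito_prefixes = cells$mito_prefixes
  )
  structure(list(cells = kept, report = report, keep = keep),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> kept %d of %d cells\n",
              ncol(x$cells$counts), x$report$n_total[1]))
  print(x$report)
  invisible(x)
}

#' Log-normalize single-cell counts (CP10K)
#'
#' Scales each cell's counts to a common library size and log-transforms:
#' `value = ln(1 + count * scale_factor / cell_total)`. Zeros stay zero, so
#' sparsity is preserved.
#'
#' @param cells A [cell_matrix()] or a sparse/dense genes-by-cells counts
#'   matrix.
#' @param scale_factor Library-size target; 10,000 gives counts-per-10k.
#' @return A `dgCMatrix` of normalized values, same dimensions and dimnames.
#' @export
log_normalize <- function(cells, scale_factor = 1e4) {
  counts <- if (inherits(cells, "cell_matrix")) cells$counts else {
    methods::as(methods::as(cells, "CsparseMatrix"), "generalMatrix")
  }
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop("cannot normalize cells with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out <- counts
  # per-entry cell total, expanded along the CSC column pointer
  out@x <- log1p(counts@x * scale_factor / rep(totals, diff(counts@p)))
  out
}

#' Gene-set module score with expression-matched control genes
#'
#' Per-cell gene-set activity score in the style of Seurat's
#' `AddModuleScore`: all genes are ranked by their average expression across
#' cells and divided into `n_bins` equal-frequency bins; for every gene-set
#' member, `n_ctrl` control genes are drawn from that member's bin (excluding
#' gene-set members; without replacement, falling back to replacement when
#' the bin is smaller than `n_ctrl`). The score of a cell is the mean
#' expression of the set genes minus the mean expression of the pooled
#' control draws, so a random gene set scores near zero by construction.
#'
#' @param norm_expr Genes-by-cells normalized expression
#'   (e.g. [log_normalize()] output); sparse or dense.
#' @param gene_set Character vector of gene symbols (matched
#'   case-insensitively); a name attached via `set_name` labels the result.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes drawn per set gene (default 100).
#' @param seed Integer seed for the control draws; recorded in the result.
#' @param set_name Label for the gene set.
#' @return A tibble of class `module_scores` with `barcode` and `score`
#'   (expression units, centred against the controls), carrying `set_name`,
#'   `n_bins`, `n_ctrl`, `seed` and the control gene draws as attributes.
#' @export
module_score <- function(norm_expr, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 0L, set_name = "module") {
  if (inherits(norm_expr, "cell_matrix")) {
    stop("module_score expects a normalized matrix; run log_normalize() first",
         call. = FALSE)
  }
  x <- methods::as(methods::as(norm_expr, "CsparseMatrix"), "generalMatrix")
  n_genes <- nrow(x)
  if (n_bins > n_genes) {
    stop("n_bins may not exceed the number of genes", call. = FALSE)
  }
  idx <- match(norm_gene(gene_set), norm_gene(rownames(x)))
  missing <- gene_set[is.na(idx)]
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    stop("no gene-set genes found in the matrix; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  avg <- Matrix::rowMeans(x)
  # equal-frequency bins; ties broken by stable gene order
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk * n_bins / n_genes)
  bin[bin < 1L] <- 1L

  in_set <- logical(n_genes)
  in_set[idx] <- TRUE
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(idx, function(g) {
      pool <- which(bin == bin[g] & !in_set)
      if (length(pool) == 0L) return(integer(0))
      if (length(pool) >= n_ctrl) {
        sample(pool, n_ctrl, replace = FALSE)
      } else {
        sample(pool, n_ctrl, replace = TRUE)
      }
    }))
  })
  if (length(ctrl) == 0L) {
    stop("no control genes available outside the gene set", call. = FALSE)
  }
  set_mean <- Matrix::colMeans(x[idx, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(x[ctrl, , drop = FALSE])
  out <- tibble::tibble(
    barcode = colnames(x) %||% as.character(seq_len(ncol(x))),
    score = as.numeric(set_mean - ctrl_mean)
  )
  attr(out, "set_name") <- set_name
  attr(out, "n_bins") <- n_bins
  attr(out, "n_ctrl") <- n_ctrl
  attr(out, "seed") <- seed
  attr(out, "missing_genes") <- missing
  attr(out, "control_genes") <- rownames(x)[ctrl]
  class(out) <- c("module_scores", class(out))
  out
}

#' Compare a per-cell score between two groups
#'
#' Unpaired two-sided t-test between two cell groups (e.g. tumour- versus
#' blood-derived immune cells). Welch's unequal-variance form is the default;
#' `var_equal = TRUE` gives the classical Student test.
#'
#' @param scores Numeric per-cell values.
#' @param labels Group labels, exactly two distinct values; the first factor
#'   level is group 1.
#' @param var_equal Assume equal variances?
#' @return One-row tibble with `group1`, `group2`, `mean1`, `mean2`,
#'   `mean_diff` (`mean1 - mean2`), `t_statistic`, `df`, `p_value`, `method`.
#' @examples
#' compare_groups(c(1, 2, 3, 4, 5, 6),
#'                rep(c("tumour", "blood"), each = 3))
#' @export
compare_groups <- function(scores, labels, var_equal = FALSE) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(f) != 2L) {
    stop("labels must define exactly two groups", call. = FALSE)
  }
  n <- table(f)
  if (any(n < 2L)) {
    stop("each group needs at least 2 observations; got ",
         paste(sprintf("%s=%d", names(n), n), collapse = ", "), call. = FALSE)
  }
  g1 <- scores[f == levels(f)[1L]]
  g2 <- scores[f == levels(f)[2L]]
  tt <- stats::t.test(g1, g2, var.equal = var_equal,
                      alternative = "two.sided")
  tibble::tibble(
    group1 = levels(f)[1L], group2 = levels(f)[2L],
    mean1 = mean(g1), mean2 = mean(g2),
    mean_diff = mean(g1) - mean(g2),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    method = if (var_equal) "student" else "welch"
  )
}
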