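#' Z-score a numeric vector
#'
#' Centred and scaled with the sample standard deviation (ddof = 1) over
#' non-missing entries. Degenerate inputs (fewer than two non-missing values,
#' or zero variance) map to all zeros rather than NaN so that a constant layer
#' contributes nothing to a downstream mean of z-scores. `NA`s propagate.
#'
#' @param x Numeric vector, length >= 1.
#' @return Numeric vector of the same length.
#' @examples
#' zscore(c(1, 2, 3))    # -1, 0, 1
#' zscore(c(5, 5, 5))    #  0, 0, 0
#' @export
zscore <- function(x) {
  if (length(x) == 0L) stop("cannot z-score an empty vector", call. = FALSE)
  stopifnot(is.numeric(x))
  out <- as.numeric(x)
  ok <- !is.na(out)
  n <- sum(ok)
  if (n == 0L) return(out)
  m <- mean(out[ok])
  s <- if (n < 2L) 0 else stats::sd(out[ok])
  out[ok] <- if (s == 0) 0 else (out[ok] - m) / s
  out
}

#' Per-steroid layer means
#'
#' Summarises one evidence layer of the integration score into a single value
#' per steroid:
#' * `concentration` — mean over patients of the (optionally log10) tissue
#'   concentration;
#' * `producing` / `receptor` — pooled grand mean of the mapped genes'
#'   expression over all samples.
#'
#' Gene symbols are matched case-insensitively after trimming whitespace.
#' Steroids with no mapped (or no matched) gene get `NA` for that layer;
#' missing concentrations are excluded from means.
#'
#' @param x For the concentration layer a steroids-by-patients matrix; for
#'   gene layers a genes-by-samples expression matrix.
#' @param map Steroid–gene map tibble ([steroid_gene_map()]); ignored for the
#'   concentration layer (row names of `x` are used).
#' @param layer One of `"concentration"`, `"producing"`, `"receptor"`.
#' @param log_conc Log10-transform concentrations before averaging?
#' @param conc_floor Pseudo-floor added before the log (concentrations span
#'   orders of magnitude; the floor keeps zeros finite). In ng/g.
#' @return Named numeric vector of per-steroid layer means. For gene layers
#'   the unmatched map genes are attached as attribute `"unmatched"`.
#' @export
layer_summary <- function(x, map = NULL,
                          layer = c("concentration", "producing", "receptor"),
                          log_conc = TRUE, conc_floor = 1e-3) {
  layer <- match.arg(layer)
  stopifnot(is.matrix(x))
  if (layer == "concentration") {
    vals <- x
    if (any(vals < 0, na.rm = TRUE)) {
      stop("concentrations must be non-negative", call. = FALSE)
    }
    if (log_conc) vals <- log10(vals + conc_floor)
    return(rowMeans(vals, na.rm = TRUE))
  }
  stopifnot(!is.null(map))
  expr_genes <- norm_gene(rownames(x))
  gene_lists <- map[[if (layer == "producing") "producing" else "receptor"]]
  unmatched <- character()
  out <- vapply(gene_lists, function(genes) {
    if (length(genes) == 0L) return(NA_real_)
    idx <- match(norm_gene(genes), expr_genes)
    miss <- genes[is.na(idx)]
    if (length(miss)) unmatched <<- c(unmatched, miss)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(NA_real_)
    mean(x[idx, , drop = FALSE], na.rm = TRUE) # pooled grand mean
  }, numeric(1))
  names(out) <- map$steroid
  # all-NA because no mapped gene matched is an input error; all-NA because
  # the map simply lists no genes is a legitimately absent layer
  if (all(is.na(out)) && length(unmatched) > 0L) {
    stop("no ", layer, " genes matched the expression matrix; unmatched: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  attr(out, "unmatched") <- unique(unmatched)
  out
}

#' Integrative per-steroid score across concentration and expression layers
#'
#' The package's core statistic: for every steroid, three evidence layers are
#' summarised (mean tissue concentration across patients; mean expression of
#' the steroid's producing-enzyme genes; mean expression of its receptor
#' genes), each layer vector is z-scored *across steroids*, and the overall
#' score is the row mean of the available layer z-scores. Ranking the overall
#' scores identifies the steroid with the strongest combined metabolomic and
#' transcriptomic signal in the tissue (in TNBC tumours this flags the
#' glucocorticoid axis, cortisol in particular).
#'
#' @param conc Steroids-by-patients concentration matrix (ng/g, non-negative,
#'   `NA` allowed).
#' @param expr Genes-by-samples normalized bulk expression matrix.
#' @param map Steroid–gene map tibble ([steroid_gene_map()]).
#' @param log_conc,conc_floor See [layer_summary()].
#' @param per_sample_z Alternative formulation: z-score across steroids
#'   within every patient/sample first, then average the per-sample z-scores.
#'   Off by default; see the methods vignette for why the average-then-z
#'   formulation is the primary one.
#' @return A tibble of class `steroid_scores`, one row per steroid shared
#'   between `conc` and `map`, with columns `steroid`, `mean_conc`,
#'   `mean_producing`, `mean_receptor`, `z_conc`, `z_producing`, `z_receptor`,
#'   `overall_score` and `rank` (1 = highest score; ties broken by steroid
#'   label). Unmatched map genes are attached as attribute `"unmatched"`.
#' @examples
#' map <- steroid_gene_map(c("cortisol", "testosterone"),
#'                         producing = list("CYP11B1", "HSD17B3"),
#'                         receptor = list("NR3C1", "AR"))
#' conc <- matrix(c(80, 120, 2, 3), 2, 2, byrow = TRUE,
#'                dimnames = list(c("cortisol", "testosterone"), c("P1", "P2")))
#' expr <- matrix(rnorm(8, 5), 4, 2,
#'                dimnames = list(c("CYP11B1", "HSD17B3", "NR3C1", "AR"),
#'                                c("S1", "S2")))
#' steroid_overall_score(conc, expr, map)
#' @export
steroid_overall_score <- function(conc, expr, map,
                                  log_conc = TRUE, conc_floor = 1e-3,
                                  per_sample_z = FALSE) {
  stopifnot(is.matrix(conc), is.matrix(expr))
  shared <- intersect(map$steroid, rownames(conc))
  if (length(shared) < 2L) {
    stop("need at least two steroids shared between the concentration ",
         "matrix and the map (z-scores across steroids are undefined ",
         "otherwise)", call. = FALSE)
  }
  map <- map[match(shared, map$steroid), , drop = FALSE]
  conc <- conc[shared, , drop = FALSE]

  if (per_sample_z) {
    layers <- per_sample_layers(conc, expr, map, log_conc, conc_floor)
  } else {
    layers <- list(
      conc = layer_summary(conc, layer = "concentration",
                           log_conc = log_conc, conc_floor = conc_floor),
      producing = layer_summary(expr, map, "producing"),
      receptor = layer_summary(expr, map, "receptor")
    )
  }
  unmatched <- unique(c(attr(layers$producing, "unmatched"),
                        attr(layers$receptor, "unmatched")))

  z <- lapply(layers, function(v) {
    if (all(is.na(v))) v else zscore(as.numeric(v))
  })
  dropped <- names(z)[vapply(z, function(v) all(is.na(v)), logical(1))]
  if (length(dropped)) {
    warning("layer(s) with no data dropped from the overall score: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  zmat <- cbind(conc = z$conc, producing = z$producing, receptor = z$receptor)
  overall <- rowMeans(zmat, na.rm = TRUE)
  overall[is.nan(overall)] <- NA_real_

  out <- tibble::tibble(
    steroid = shared,
    mean_conc = as.numeric(layers$conc),
    mean_producing = as.numeric(layers$producing),
    mean_receptor = as.numeric(layers$receptor),
    z_conc = unname(zmat[, "conc"]),
    z_producing = unname(zmat[, "producing"]),
    z_receptor = unname(zmat[, "receptor"]),
    overall_score = unname(overall)
  )
  # descending score; ties resolved lexicographically on the steroid label
  ord <- order(-out$overall_score, out$steroid)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out <- out[order(out$rank), , drop = FALSE]
  attr(out, "unmatched") <- unmatched
  class(out) <- c("steroid_scores", class(out))
  out
}

# Alternative interpretation: z across steroids within each sample, then
# average the z-scores over samples.
per_sample_layers <- function(conc, expr, map, log_conc, conc_floor) {
  conc_vals <- if (log_conc) log10(conc + conc_floor) else conc
  zcols <- function(m) apply(m, 2L, zscore)
  conc_z <- rowMeans(zcols(conc_vals), na.rm = TRUE)

  gene_layer <- function(field) {
    expr_genes <- norm_gene(rownames(expr))
    per_steroid <- t(vapply(map[[field]], function(genes) {
      idx <- match(norm_gene(genes), expr_genes)
      idx <- idx[!is.na(idx)]
      if (length(idx) == 0L) return(rep(NA_real_, ncol(expr)))
      colMeans(expr[idx, , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(expr))))
    keep <- !apply(per_steroid, 1L, function(r) all(is.na(r)))
    z <- matrix(NA_real_, nrow(per_steroid), ncol(per_steroid))
    if (any(keep)) {
      z[keep, ] <- apply(per_steroid[keep, , drop = FALSE], 2L, zscore)
    }
    out <- rowMeans(z, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    names(out) <- map$steroid
    out
  }
  list(conc = conc_z, producing = gene_layer("producing"),
       receptor = gene_layer("receptor"))
}

#' @export
print.steroid_scores <- function(x, ...) {
  cat("Integrative steroid scores (", nrow(x), " steroids)\n", sep = "")
  NextMethod()
}
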