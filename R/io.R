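#' Read a labelled numeric matrix from TSV/CSV
#'
#' Reads a delimited file whose first row holds column labels and whose first
#' column holds row labels, returning a base numeric matrix with `dimnames`.
#' This is the on-disk representation used for concentration, expression and
#' immune-fraction matrices throughout the package.
#'
#' @param path Path to an existing TSV or CSV file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return A numeric matrix with unique row and column names, in file order.
#'   Empty cells and literal `NA` become `NA`.
#' @seealso [write_matrix()] for the inverse; the pair round-trips exactly.
#' @export
read_matrix <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("matrix file does not exist: ", path, call. = FALSE)
  }
  delim <- if (format == "tsv") "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE,
    na = character() # handle NA ourselves so we can flag true parse errors
  )
  if (ncol(raw) < 2L) {
    stop("expected at least one label column and one data column in ", path,
         call. = FALSE)
  }
  row_labels <- raw[[1L]]
  col_labels <- colnames(raw)[-1L]
  if (anyDuplicated(row_labels)) {
    dup <- unique(row_labels[duplicated(row_labels)])
    stop("duplicated row label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(col_labels)) {
    dup <- unique(col_labels[duplicated(col_labels)])
    stop("duplicated column label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !(is.na(cells) | cells %in% c("", "NA")),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric value %s at row '%s', column '%s'",
      dQuote(cells[bad[1L, , drop = FALSE]]),
      row_labels[bad[1L, 1L]], col_labels[bad[1L, 2L]]
    ), call. = FALSE)
  }
  dimnames(num) <- list(row_labels, col_labels)
  num
}

#' Write a labelled numeric matrix to TSV/CSV
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param id_col Header used for the row-label column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("tsv", "csv"), id_col = "id") {
  format <- match.arg(format)
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- tibble::as_tibble(x, rownames = id_col)
  if (format == "tsv") {
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Steroid -> gene map

#' Construct a steroid–gene map
#'
#' Associates each steroid with the genes encoding its biosynthetic enzymes
#' ("producing" genes) and its nuclear receptors. The package ships a small
#' KEGG-style default for the major steroid classes under
#' `system.file("extdata", "steroid_gene_map.json", package = "steroidscope")`;
#' the map is ordinary user data and can be edited freely.
#'
#' @param steroid Character vector of unique steroid identifiers.
#' @param producing,receptor Lists of character vectors (one per steroid);
#'   empty vectors are allowed, `NULL` entries are not.
#' @return A tibble with columns `steroid`, `producing` and `receptor`
#'   (list-columns of gene symbols).
#' @export
steroid_gene_map <- function(steroid, producing, receptor) {
  steroid <- as.character(steroid)
  if (anyDuplicated(steroid)) {
    stop("steroid identifiers must be unique", call. = FALSE)
  }
  stopifnot(length(producing) == length(steroid),
            length(receptor) == length(steroid))
  check_lists <- function(l, what) {
    if (any(vapply(l, is.null, logical(1)))) {
      stop(what, " gene lists may be empty but not NULL", call. = FALSE)
    }
    lapply(l, function(g) as.character(g))
  }
  tibble::tibble(
    steroid = steroid,
    producing = check_lists(producing, "producing"),
    receptor = check_lists(receptor, "receptor")
  )
}

#' Read / write a steroid–gene map as JSON
#'
#' The JSON layout is `{"<steroid>": {"producing": [...], "receptor": [...]}}`.
#'
#' @param path JSON file path.
#' @return `read_steroid_map()` returns the map tibble; `write_steroid_map()`
#'   returns `path` invisibly.
#' @export
read_steroid_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  steroid_gene_map(
    steroid = names(obj),
    producing = unname(lapply(obj, function(e) as.character(e$producing))),
    receptor = unname(lapply(obj, function(e) as.character(e$receptor)))
  )
}

#' @rdname read_steroid_map
#' @param map A steroid–gene map tibble from [steroid_gene_map()].
#' @export
write_steroid_map <- function(map, path) {
  obj <- stats::setNames(
    purrr::map2(map$producing, map$receptor,
                function(p, r) list(producing = p, receptor = r)),
    map$steroid
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

# Gene symbols are matched case-insensitively after trimming whitespace.
norm_gene <- function(x) toupper(trimws(x))

# ---------------------------------------------------------------------------
# Single-cell counts container

#' Per-cell QC metadata from a counts matrix
#'
#' @param counts Sparse or dense genes-by-cells matrix of non-negative
#'   integer counts with dimnames.
#' @param group Optional per-cell group labels (e.g. `"tumour"` / `"blood"`).
#' @param mito_prefixes Gene-name prefixes identifying mitochondrial genes.
#' @return Tibble with `barcode`, optional `group`, `n_genes` (genes with
#'   count > 0), `n_umi` (column sum) and `pct_mito` (percent of counts on
#'   mitochondrial genes; 0 for empty cells).
#' @export
cell_metadata <- function(counts, group = NULL,
                          mito_prefixes = c("MT-", "mt-")) {
  counts <- methods::as(counts, "CsparseMatrix")
  n_umi <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  pat <- paste0("^(", paste(sapply(mito_prefixes, escape_regex),
                            collapse = "|"), ")")
  is_mito <- grepl(pat, rownames(counts))
  mito_umi <- if (any(is_mito)) {
    Matrix::colSums(counts[is_mito, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  bc <- colnames(counts)
  if (is.null(bc)) bc <- as.character(seq_len(ncol(counts)))
  meta <- tibble::tibble(
    barcode = bc,
    n_genes = as.integer(n_genes),
    n_umi = as.integer(round(n_umi)),
    pct_mito = ifelse(n_umi > 0, 100 * mito_umi / n_umi, 0)
  )
  if (!is.null(group)) {
    stopifnot(length(group) == ncol(counts))
    meta <- dplyr::mutate(meta, group = as.character(group),
                          .after = "barcode")
  }
  meta
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x)

#' Single-cell counts with consistent per-cell metadata
#'
#' Bundles a sparse genes-by-cells integer count matrix with per-cell QC
#' covariates recomputed from the matrix itself, so the two can never drift
#' apart.
#'
#' @inheritParams cell_metadata
#' @return An object of class `cell_matrix`: a list with `counts`
#'   (`dgCMatrix`), `meta` (tibble from [cell_metadata()]) and
#'   `mito_prefixes`.
#' @export
cell_matrix <- function(counts, group = NULL, mito_prefixes = c("MT-", "mt-")) {
  if (inherits(counts, "sparseMatrix") && !methods::is(counts, "dMatrix")) {
    counts <- methods::as(counts, "dMatrix") # e.g. pattern matrices from MTX
  }
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stop("counts must carry gene (row) and barcode (column) names",
         call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    dimnames(counts) <- list(rownames(counts) %||% character(0),
                             colnames(counts) %||% character(0))
  }
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(
      counts = counts,
      meta = cell_metadata(counts, group = group,
                           mito_prefixes = mito_prefixes),
      mito_prefixes = mito_prefixes
    ),
    class = "cell_matrix"
  )
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells, %d nonzero counts\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  print(utils::head(x$meta, 5))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Read sparse single-cell counts (Matrix Market triplet)
#'
#' Reads the standard `.mtx` + features + barcodes triplet. Feature and
#' barcode files are plain text, one identifier per line (a first
#' tab-separated field is used if more columns are present).
#'
#' @param mtx_path Matrix Market file of genes-by-cells counts.
#' @param features_path,barcodes_path One identifier per line.
#' @param group Optional per-cell group labels, or a two-column
#'   (barcode, group) TSV path.
#' @inheritParams cell_metadata
#' @return A [cell_matrix()].
#' @export
read_sparse_counts <- function(mtx_path, features_path, barcodes_path,
                               group = NULL,
                               mito_prefixes = c("MT-", "mt-")) {
  m <- Matrix::readMM(mtx_path)
  features <- first_field(readr::read_lines(features_path, progress = FALSE))
  barcodes <- first_field(readr::read_lines(barcodes_path, progress = FALSE))
  if (length(features) != nrow(m)) {
    stop(sprintf("features file has %d entries but matrix declares %d rows",
                 length(features), nrow(m)), call. = FALSE)
  }
  if (length(barcodes) != ncol(m)) {
    stop(sprintf("barcodes file has %d entries but matrix declares %d columns",
                 length(barcodes), ncol(m)), call. = FALSE)
  }
  dimnames(m) <- list(features, barcodes)
  if (is.character(group) && length(group) == 1L && file.exists(group)) {
    tab <- readr::read_tsv(group, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE,
      show_col_types = FALSE)
    group <- if ("group" %in% names(tab)) {
      tab[["group"]][match(barcodes, tab[[1L]])]
    } else {
      NULL
    }
  }
  cell_matrix(m, group = group, mito_prefixes = mito_prefixes)
}

first_field <- function(lines) {
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write sparse single-cell counts as a Matrix Market triplet
#'
#' @param cells A [cell_matrix()].
#' @param dir Output directory (created if missing). Writes `counts.mtx`,
#'   `features.tsv`, `barcodes.tsv` and `cell_metadata.tsv`.
#' @return The directory, invisibly.
#' @export
write_sparse_counts <- function(cells, dir) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- tryCatch(
    Matrix::writeMM(cells$counts, file.path(dir, "counts.mtx")),
    error = function(e) stop("failed to write ", file.path(dir, "counts.mtx"),
                             ": ", conditionMessage(e), call. = FALSE)
  )
  readr::write_lines(rownames(cells$counts), file.path(dir, "features.tsv"))
  readr::write_lines(colnames(cells$counts), file.path(dir, "barcodes.tsv"))
  readr::write_tsv(cells$meta, file.path(dir, "cell_metadata.tsv"),
                   progress = FALSE)
  invisible(dir)
}
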