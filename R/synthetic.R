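# Canonical steroid panel used by the synthetic cohort (the 31 hormones a
# targeted steroid LC-MS/MS panel typically resolves in tumour tissue).
steroid_panel <- c(
  "cortisol", "cortisone", "corticosterone", "11-deoxycortisol",
  "11-deoxycorticosterone", "18-hydroxycorticosterone", "aldosterone",
  "pregnenolone", "17-hydroxypregnenolone", "progesterone",
  "17-hydroxyprogesterone", "21-deoxycortisol", "allopregnanolone",
  "pregnanolone", "DHEA", "DHEA-S", "androstenedione", "androstenediol",
  "testosterone", "epitestosterone", "dihydrotestosterone", "androsterone",
  "etiocholanolone", "7a-hydroxy-DHEA", "16a-hydroxy-DHEA", "estrone",
  "estradiol", "estriol", "tetrahydrocortisol", "tetrahydrocortisone",
  "20a-dihydroprogesterone"
)

# LM22-style immune population labels (deconvolution output format).
lm22_populations <- c(
  "B cells naive", "B cells memory", "Plasma cells", "T cells CD8",
  "T cells CD4 naive", "T cells CD4 memory resting",
  "T cells CD4 memory activated", "T cells follicular helper",
  "T cells regulatory (Tregs)", "T cells gamma delta", "NK cells resting",
  "NK cells activated", "Monocytes", "Macrophages M0", "Macrophages M1",
  "Macrophages M2", "Dendritic cells resting", "Dendritic cells activated",
  "Mast cells resting", "Mast cells activated", "Eosinophils", "Neutrophils"
)

mito_gene_names <- c(
  "MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5", "MT-ND6",
  "MT-CO1", "MT-CO2", "MT-CO3", "MT-ATP6", "MT-ATP8", "MT-CYB"
)

#' Configuration for the synthetic TNBC cohort
#'
#' Defines every dimension, noise level and planted effect of the synthetic
#' cohort bundle. Defaults mirror the study conditions the pipeline targets:
#' 16 patients with steroid concentrations for 31 steroids, 360 bulk RNA-seq
#' samples, 200 single cells per group, and planted effects large enough to
#' be recoverable by the downstream analyses (see the methods vignette for
#' the reasoning behind each default).
#'
#' @param seed Integer; fixes every random draw in the bundle.
#' @param n_patients Patients with steroid concentration data.
#' @param n_steroids Steroids on the panel.
#' @param n_bulk_samples Bulk RNA-seq samples (also rows of the fraction
#'   matrix).
#' @param n_bulk_genes Total genes in the bulk expression matrix (mapped
#'   genes plus background).
#' @param n_sc_genes Genes in the single-cell counts matrix.
#' @param n_cells_per_group Cells per group (tumour / blood).
#' @param planted_steroid Steroid elevated in all three evidence layers.
#' @param effect_conc,effect_producing,effect_receptor Planted elevations
#'   (natural-log units) of the planted steroid's concentration, producing
#'   genes and receptor genes.
#' @param receptor_dominance Extra elevation (log-units) of the planted
#'   steroid's first receptor gene, making it the dominant receptor.
#' @param planted_cor Tibble with columns `gene`, `population`, `sign`
#'   (+1/-1) describing the planted receptor-fraction correlations;
#'   `NULL` installs the default pattern (planted receptor positively
#'   coupled to M2 macrophages, negatively to activated dendritic cells and
#'   M1 macrophages).
#' @param cor_strength Log-linear modulation weight of the Dirichlet
#'   concentrations per standardized receptor-expression unit; the default
#'   0.2 yields planted correlations of about |r| = 0.4.
#' @param signature_size Genes in the planted steroid-biosynthesis signature
#'   set.
#' @param signature_delta Log-unit boost of signature-gene means in
#'   tumour-group cells.
#' @param conc_meanlog_mu,conc_meanlog_sd Hyperparameters of the per-steroid
#'   lognormal location (drawn once per steroid).
#' @param conc_sdlog Lognormal sigma of concentrations across patients.
#' @param expr_baseline_mean,expr_baseline_sd,expr_noise_sd Bulk expression
#'   model: per-gene baseline ~ Normal(mean, sd); per-sample noise sd.
#' @param nb_size Negative-binomial dispersion (size) of single-cell counts.
#' @param sc_meanlog,sc_sdlog Lognormal hyperparameters of per-gene
#'   single-cell mean counts.
#' @param n_ihc_regions_per_class IHC regions simulated per region class.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_patients = 16L,
                          n_steroids = 31L,
                          n_bulk_samples = 360L,
                          n_bulk_genes = 1200L,
                          n_sc_genes = 1000L,
                          n_cells_per_group = 200L,
                          planted_steroid = "cortisol",
                          effect_conc = 2,
                          effect_producing = 2,
                          effect_receptor = 2,
                          receptor_dominance = 1,
                          planted_cor = NULL,
                          cor_strength = 0.2,
                          signature_size = 25L,
                          signature_delta = 0.5,
                          conc_meanlog_mu = 1,
                          conc_meanlog_sd = 1,
                          conc_sdlog = 0.8,
                          expr_baseline_mean = 3,
                          expr_baseline_sd = 1,
                          expr_noise_sd = 1,
                          nb_size = 2,
                          sc_meanlog = log(0.3),
                          sc_sdlog = 1,
                          n_ihc_regions_per_class = 8L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_steroids >= 2L, cfg$n_patients >= 1L,
            cfg$effect_conc >= 0, cfg$effect_producing >= 0,
            cfg$effect_receptor >= 0, cfg$signature_delta >= 0,
            cfg$cor_strength >= 0, cfg$nb_size > 0)
  cfg$seed <- as.integer(seed)
  steroids <- if (cfg$n_steroids <= length(steroid_panel)) {
    steroid_panel[seq_len(cfg$n_steroids)]
  } else {
    c(steroid_panel,
      sprintf("steroid_%02d", seq(length(steroid_panel) + 1L, cfg$n_steroids)))
  }
  if (!cfg$planted_steroid %in% steroids) {
    stop("planted_steroid must be one of the panel steroids", call. = FALSE)
  }
  cfg$steroids <- steroids
  if (is.null(cfg$planted_cor)) {
    planted_receptor <- synth_gene(cfg$planted_steroid, "RC", 1L)
    cfg$planted_cor <- tibble::tibble(
      gene = planted_receptor,
      population = c("Macrophages M2", "Dendritic cells activated",
                     "Macrophages M1"),
      sign = c(1, -1, -1)
    )
  }
  mapped <- cfg$n_steroids * 5L # 3 producing + 2 receptor genes per steroid
  if (cfg$n_bulk_genes < mapped) {
    stop("n_bulk_genes must be at least ", mapped,
         " to hold the mapped genes", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

synth_gene <- function(steroid, kind, i) {
  base <- toupper(gsub("[^A-Za-z0-9]+", "", steroid))
  sprintf("%s_%s%d", base, kind, i)
}

synthetic_map <- function(cfg) {
  steroid_gene_map(
    steroid = cfg$steroids,
    producing = lapply(cfg$steroids, function(s)
      vapply(1:3, function(i) synth_gene(s, "PG", i), character(1))),
    receptor = lapply(cfg$steroids, function(s)
      vapply(1:2, function(i) synth_gene(s, "RC", i), character(1)))
  )
}

#' Generate a synthetic cohort bundle
#'
#' Draws a full multi-omics cohort with known, recorded ground truth:
#' * concentrations — lognormal per steroid, with the planted steroid's
#'   location shifted up by `effect_conc`;
#' * bulk expression — Gaussian on the log scale around per-gene baselines,
#'   with the planted steroid's producing and receptor genes elevated;
#' * immune fractions — Dirichlet on the simplex, with planted populations'
#'   concentrations modulated log-linearly by standardized receptor
#'   expression, planting signed correlations;
#' * single-cell counts — negative binomial with lognormal per-gene means,
#'   mitochondrial genes, per-cell library-size factors, and the signature
#'   set boosted by `signature_delta` log-units in tumour-group cells;
#' * IHC regions — immune-infiltrated regions drawn from a higher staining
#'   intensity distribution than tumour/stroma regions.
#'
#' All randomness flows from `config$seed` through per-component sub-seeds,
#' so any subset of components reproduces the exact values it would have in
#' the full bundle.
#'
#' @param config A [cohort_config()].
#' @param components Which components to generate; the steroid map and
#'   ground-truth record are always included (fractions imply expression).
#' @return A list of class `steroid_cohort` with elements `concentrations`
#'   (steroids x patients), `expression` (genes x samples), `map`,
#'   `fractions` (samples x populations), `cells` ([cell_matrix()]),
#'   `ihc_regions` (tibble), `ground_truth` and `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            components = c("concentrations", "expression",
                                           "fractions", "cells", "ihc")) {
  stopifnot(inherits(config, "cohort_config"))
  components <- match.arg(components, several.ok = TRUE)
  if ("fractions" %in% components) {
    components <- union(components, "expression")
  }
  sub <- withr::with_seed(config$seed,
                          sample.int(.Machine$integer.max - 1L, 5L))
  names(sub) <- c("concentrations", "expression", "fractions", "cells", "ihc")

  map <- synthetic_map(config)
  planted_receptor <- map$receptor[[
    match(config$planted_steroid, map$steroid)]][1L]

  bundle <- list(map = map, config = config)

  if ("concentrations" %in% components) {
    bundle$concentrations <- withr::with_seed(
      sub[["concentrations"]], gen_concentrations(config))
  }
  if ("expression" %in% components) {
    bundle$expression <- withr::with_seed(
      sub[["expression"]], gen_expression(config, map))
  }
  if ("fractions" %in% components) {
    bundle$fractions <- withr::with_seed(
      sub[["fractions"]],
      gen_fractions(config, bundle$expression))
  }
  if ("cells" %in% components) {
    sc <- withr::with_seed(sub[["cells"]], gen_cells(config))
    bundle$cells <- sc$cells
    bundle$signature_genes <- sc$signature_genes
  }
  if ("ihc" %in% components) {
    bundle$ihc_regions <- withr::with_seed(sub[["ihc"]], gen_ihc(config))
  }

  bundle$ground_truth <- list(
    planted_steroid = config$planted_steroid,
    planted_receptor = planted_receptor,
    effects = list(conc = config$effect_conc,
                   producing = config$effect_producing,
                   receptor = config$effect_receptor),
    receptor_dominance = config$receptor_dominance,
    planted_cor = config$planted_cor,
    signature_genes = bundle$signature_genes,
    signature_delta = config$signature_delta,
    conc_meanlog = attr(bundle$concentrations, "meanlog"),
    conc_sdlog = config$conc_sdlog,
    seed = config$seed
  )
  structure(bundle, class = "steroid_cohort")
}

gen_concentrations <- function(cfg) {
  meanlog <- stats::rnorm(cfg$n_steroids, cfg$conc_meanlog_mu,
                          cfg$conc_meanlog_sd)
  names(meanlog) <- cfg$steroids
  meanlog[cfg$planted_steroid] <- meanlog[cfg$planted_steroid] +
    cfg$effect_conc
  conc <- t(vapply(meanlog, function(m)
    stats::rlnorm(cfg$n_patients, meanlog = m, sdlog = cfg$conc_sdlog),
    numeric(cfg$n_patients)))
  dimnames(conc) <- list(cfg$steroids,
                         sprintf("patient_%02d", seq_len(cfg$n_patients)))
  attr(conc, "meanlog") <- meanlog
  conc
}

gen_expression <- function(cfg, map) {
  mapped <- c(unlist(map$producing), unlist(map$receptor))
  n_bg <- cfg$n_bulk_genes - length(mapped)
  genes <- c(mapped, sprintf("BG%04d", seq_len(n_bg)))
  baseline <- stats::rnorm(length(genes), cfg$expr_baseline_mean,
                           cfg$expr_baseline_sd)
  names(baseline) <- genes
  i <- match(cfg$planted_steroid, map$steroid)
  baseline[map$producing[[i]]] <- baseline[map$producing[[i]]] +
    cfg$effect_producing
  baseline[map$receptor[[i]]] <- baseline[map$receptor[[i]]] +
    cfg$effect_receptor
  baseline[map$receptor[[i]][1L]] <- baseline[map$receptor[[i]][1L]] +
    cfg$receptor_dominance
  expr <- baseline +
    matrix(stats::rnorm(length(genes) * cfg$n_bulk_samples,
                        sd = cfg$expr_noise_sd),
           length(genes), cfg$n_bulk_samples)
  dimnames(expr) <- list(genes,
                         sprintf("sample_%03d", seq_len(cfg$n_bulk_samples)))
  expr
}

gen_fractions <- function(cfg, expr) {
  pops <- lm22_populations
  # moderately uneven base composition, total concentration 100
  base <- rep(1, length(pops))
  base[pops %in% c("T cells CD8", "Macrophages M0", "Macrophages M2",
                   "Monocytes")] <- 2
  alpha0 <- 100 * base / sum(base)
  names(alpha0) <- pops

  log_alpha <- matrix(rep(log(alpha0), each = cfg$n_bulk_samples),
                      cfg$n_bulk_samples, length(pops),
                      dimnames = list(colnames(expr), pops))
  for (k in seq_len(nrow(cfg$planted_cor))) {
    g <- cfg$planted_cor$gene[k]
    p <- cfg$planted_cor$population[k]
    if (!g %in% rownames(expr)) next
    x <- as.numeric(scale(expr[g, ]))
    log_alpha[, p] <- log_alpha[, p] +
      cfg$planted_cor$sign[k] * cfg$cor_strength * x
  }
  alpha <- exp(log_alpha)
  draws <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
                  nrow(alpha), ncol(alpha), dimnames = dimnames(alpha))
  draws / rowSums(draws)
}

gen_cells <- function(cfg) {
  n_sig <- cfg$signature_size
  sig_genes <- sprintf("STS%03d", seq_len(n_sig))
  n_bg <- cfg$n_sc_genes - n_sig - length(mito_gene_names)
  stopifnot(n_bg > 0)
  genes <- c(sig_genes, mito_gene_names, sprintf("G%04d", seq_len(n_bg)))

  mu <- stats::rlnorm(length(genes), cfg$sc_meanlog, cfg$sc_sdlog)
  names(mu) <- genes
  # mitochondrial genes are high-expressed housekeeping transcripts
  mu[mito_gene_names] <- stats::rlnorm(length(mito_gene_names),
                                       log(2), 0.3)
  n_cells <- 2L * cfg$n_cells_per_group
  group <- rep(c("tumour", "blood"), each = cfg$n_cells_per_group)
  libsize <- stats::rlnorm(n_cells, 0, 0.3)

  mu_mat <- outer(mu, libsize)
  boost <- exp(cfg$signature_delta)
  mu_mat[sig_genes, group == "tumour"] <-
    mu_mat[sig_genes, group == "tumour"] * boost
  counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                                  size = cfg$nb_size),
                   nrow(mu_mat), ncol(mu_mat))
  dimnames(counts) <- list(genes,
                           sprintf("%s_cell_%04d", group, seq_len(n_cells)))
  list(cells = cell_matrix(Matrix::Matrix(counts, sparse = TRUE),
                           group = group),
       signature_genes = sig_genes)
}

gen_ihc <- function(cfg) {
  n <- cfg$n_ihc_regions_per_class
  classes <- c("immune_infiltrated", "tumour", "stroma")
  per_class <- function(cl) {
    if (cl == "immune_infiltrated") {
      intensity <- sample(2:3, n, replace = TRUE, prob = c(0.4, 0.6))
      percentage <- round(stats::runif(n, 60, 95), 1)
    } else {
      intensity <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.4, 0.1))
      percentage <- round(stats::runif(n, 5, 40), 1)
    }
    tibble::tibble(region_class = cl, intensity = intensity,
                   percentage = percentage)
  }
  out <- purrr::map_dfr(classes, per_class)
  dplyr::mutate(out,
                region_id = sprintf("region_%02d", seq_len(nrow(out))),
                .before = 1L)
}

#' @export
print.steroid_cohort <- function(x, ...) {
  cat("<steroid_cohort>\n")
  if (!is.null(x$concentrations)) {
    cat(sprintf("  concentrations: %d steroids x %d patients\n",
                nrow(x$concentrations), ncol(x$concentrations)))
  }
  if (!is.null(x$expression)) {
    cat(sprintf("  expression:     %d genes x %d samples\n",
                nrow(x$expression), ncol(x$expression)))
  }
  if (!is.null(x$fractions)) {
    cat(sprintf("  fractions:      %d samples x %d populations\n",
                nrow(x$fractions), ncol(x$fractions)))
  }
  if (!is.null(x$cells)) {
    cat(sprintf("  cells:          %d genes x %d cells\n",
                nrow(x$cells$counts), ncol(x$cells$counts)))
  }
  cat(sprintf("  planted steroid: %s\n", x$ground_truth$planted_steroid))
  invisible(x)
}

#' Write / read a cohort bundle on disk
#'
#' Serialises every component of a [generate_cohort()] bundle in the
#' pipeline's plain-text input formats (TSV matrices, JSON map and ground
#' truth, Matrix Market counts triplet), and reads such a directory back to
#' an equivalent bundle.
#'
#' @param bundle A `steroid_cohort`.
#' @param dir Target directory (created if missing; must be writable).
#' @return `write_bundle()`: `dir`, invisibly. `read_bundle()`: a
#'   `steroid_cohort` list (without the `config` object).
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "steroid_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  if (file.access(dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", dir, call. = FALSE)
  }
  wm <- function(x, f) write_matrix(x, file.path(dir, f))
  if (!is.null(bundle$concentrations)) {
    conc <- bundle$concentrations
    attr(conc, "meanlog") <- NULL
    wm(conc, "concentrations.tsv")
  }
  if (!is.null(bundle$expression)) wm(bundle$expression, "expression.tsv")
  if (!is.null(bundle$fractions)) wm(bundle$fractions, "fractions.tsv")
  write_steroid_map(bundle$map, file.path(dir, "steroid_gene_map.json"))
  if (!is.null(bundle$cells)) write_sparse_counts(bundle$cells, dir)
  if (!is.null(bundle$ihc_regions)) {
    readr::write_tsv(bundle$ihc_regions, file.path(dir, "ihc_regions.tsv"),
                     progress = FALSE)
  }
  gt <- bundle$ground_truth
  gt$planted_cor <- as.list(gt$planted_cor)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_matrix(p) else NULL
  }
  bundle <- list(
    concentrations = rd("concentrations.tsv"),
    expression = rd("expression.tsv"),
    fractions = rd("fractions.tsv"),
    map = read_steroid_map(file.path(dir, "steroid_gene_map.json"))
  )
  if (file.exists(file.path(dir, "counts.mtx"))) {
    bundle$cells <- read_sparse_counts(
      file.path(dir, "counts.mtx"),
      file.path(dir, "features.tsv"),
      file.path(dir, "barcodes.tsv"),
      group = file.path(dir, "cell_metadata.tsv")
    )
  }
  ihc_path <- file.path(dir, "ihc_regions.tsv")
  if (file.exists(ihc_path)) {
    bundle$ihc_regions <- readr::read_tsv(
      ihc_path,
      col_types = readr::cols(region_id = readr::col_character(),
                              region_class = readr::col_character(),
                              intensity = readr::col_integer(),
                              percentage = readr::col_double()),
      progress = FALSE)
  }
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    if (!is.null(gt$planted_cor)) {
      gt$planted_cor <- tibble::as_tibble(gt$planted_cor)
    }
    bundle$ground_truth <- gt
  }
  structure(bundle, class = "steroid_cohort")
}
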