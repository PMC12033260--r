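#' Run the full steroid-immune analysis pipeline
#'
#' Orchestrates simulate (or load) -> integrative steroid score ->
#' receptor/immune correlation screen -> single-cell QC, normalization and
#' module scoring -> IHC region comparison, writing machine-readable TSV/JSON
#' outputs and a run manifest. Reruns with the same configuration and seed
#' reproduce every numeric output byte for byte.
#'
#' The configuration is a YAML file (or equivalent list) with blocks:
#' \preformatted{
#' seed: 1
#' out_dir: results/run1        # optional; defaults next to the config
#' simulate: true               # or false with an `inputs:` block of paths
#' cohort: {n_patients: 16}     # overrides for cohort_config()
#' score: {log_conc: true, per_sample_z: false}
#' correlate: {genes: [..], adjust: table}   # default: all receptor genes
#' sc: {dialect: inhouse, n_bins: 24, n_ctrl: 100, gene_set: null}
#' }
#' When `simulate: false`, `inputs:` must name existing files:
#' `concentrations`, `expression`, `map`, `fractions`, `mtx`, `features`,
#' `barcodes`, `cell_metadata`, `ihc_regions`. Validation happens before any
#' computation, so an invalid configuration never leaves partial outputs.
#'
#' @param config Path to a YAML configuration file, or a named list.
#' @param out_dir Output directory; overrides the configuration's `out_dir`.
#' @return The run manifest (list of class `run_manifest`), invisibly
#'   written to `manifest.json`: configuration hash, seed, per-stage status,
#'   timing and output paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) {
    stop("configuration must provide out_dir (or pass out_dir=)",
         call. = FALSE)
  }
  validate_run_config(cfg) # pre-flight: fails before any compute
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  manifest <- list(
    package = as.character(utils::packageVersion("steroidscope")),
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    seed = cfg$seed,
    stages = list()
  )
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    log_msg("stage %s: start", name)
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    el <- proc.time()[["elapsed"]] - t0
    log_msg("stage %s: done in %.2fs", name, el)
    manifest$stages[[name]] <<- list(
      name = name, status = "ok", elapsed_s = round(el, 3),
      outputs = res
    )
    res
  }
  outp <- function(f) file.path(cfg$out_dir, f)

  # ---- stage 1: simulate or load -----------------------------------------
  bundle <- NULL
  stage("inputs", function() {
    if (isTRUE(cfg$simulate)) {
      cc <- do.call(cohort_config, c(list(seed = cfg$seed), cfg$cohort))
      bundle <<- generate_cohort(cc)
      write_bundle(bundle, outp("cohort"))
      file.path("cohort", c("concentrations.tsv", "expression.tsv",
                            "fractions.tsv", "steroid_gene_map.json",
                            "counts.mtx", "ihc_regions.tsv"))
    } else {
      inp <- cfg$inputs
      bundle <<- list(
        concentrations = read_matrix(inp$concentrations),
        expression = read_matrix(inp$expression),
        map = read_steroid_map(inp$map),
        fractions = read_matrix(inp$fractions),
        cells = read_sparse_counts(inp$mtx, inp$features, inp$barcodes,
                                   group = inp$cell_metadata),
        ihc_regions = readr::read_tsv(inp$ihc_regions,
                                      show_col_types = FALSE,
                                      progress = FALSE)
      )
      character(0)
    }
  })

  # ---- stage 2: integrative steroid score --------------------------------
  stage("score", function() {
    sc <- cfg$score
    scores <- steroid_overall_score(
      bundle$concentrations, bundle$expression, bundle$map,
      log_conc = sc$log_conc %||% TRUE,
      per_sample_z = sc$per_sample_z %||% FALSE
    )
    readr::write_tsv(scores, outp("steroid_scores.tsv"), progress = FALSE)
    "steroid_scores.tsv"
  })

  # ---- stage 3: receptor / immune-fraction screen ------------------------
  stage("correlate", function() {
    genes <- cfg$correlate$genes %||% unique(unlist(bundle$map$receptor))
    screen <- receptor_immune_screen(
      bundle$expression, bundle$fractions, genes,
      adjust = cfg$correlate$adjust %||% "table"
    )
    readr::write_tsv(screen, outp("correlations.tsv"), progress = FALSE)
    "correlations.tsv"
  })

  # ---- stage 4: single-cell QC + normalization + module score ------------
  stage("sc_score", function() {
    sc <- cfg$sc
    thr <- qc_thresholds(sc$dialect %||% "inhouse")
    qc <- qc_filter(bundle$cells, thr)
    readr::write_tsv(qc$report, outp("qc_report.tsv"), progress = FALSE)
    norm <- log_normalize(qc$cells, scale_factor = sc$scale_factor %||% 1e4)
    gene_set <- sc$gene_set %||% bundle$signature_genes %||%
      bundle$ground_truth$signature_genes
    if (is.character(gene_set) && length(gene_set) == 1L &&
        file.exists(gene_set)) {
      gene_set <- readr::read_lines(gene_set, progress = FALSE)
    }
    if (is.null(gene_set)) {
      stop("sc.gene_set must be provided when the cohort is not simulated",
           call. = FALSE)
    }
    scores <- module_score(norm, gene_set,
                           n_bins = sc$n_bins %||% 24,
                           n_ctrl = sc$n_ctrl %||% 100,
                           seed = cfg$seed,
                           set_name = sc$set_name %||% "steroid_biosynthesis")
    scored <- dplyr::left_join(scores, qc$cells$meta[, c("barcode", "group")],
                               by = "barcode")
    readr::write_tsv(scored, outp("module_scores.tsv"), progress = FALSE)
    cmp <- compare_groups(scored$score,
                          factor(scored$group, levels = c("tumour", "blood")))
    readr::write_tsv(cmp, outp("group_comparison.tsv"), progress = FALSE)
    c("qc_report.tsv", "module_scores.tsv", "group_comparison.tsv")
  })

  # ---- stage 5: IHC H-scores ---------------------------------------------
  stage("ihc", function() {
    scored <- score_ihc_regions(bundle$ihc_regions)
    readr::write_tsv(scored, outp("ihc_hscores.tsv"), progress = FALSE)
    cmpr <- region_activity_compare(scored)
    readr::write_tsv(cmpr$test, outp("ihc_comparison.tsv"), progress = FALSE)
    c("ihc_hscores.tsv", "ihc_comparison.tsv")
  })

  # ---- finalise manifest -------------------------------------------------
  expected <- unlist(lapply(manifest$stages, `[[`, "outputs"))
  missing <- expected[!file.exists(file.path(cfg$out_dir, expected))]
  if (length(missing)) {
    stop("pipeline finished but output file(s) missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  manifest$complete <- TRUE
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), outp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("configuration file does not exist: ", config, call. = FALSE)
    }
    cfg <- yaml::read_yaml(config)
    if (is.null(cfg$out_dir)) {
      cfg$out_dir <- file.path(dirname(config), "steroidscope_run")
    }
    cfg
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be a YAML file path or a named list", call. = FALSE)
  }
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.numeric(cfg$seed)) {
    stop("configuration error: 'seed' must be an integer", call. = FALSE)
  }
  if (!isTRUE(cfg$simulate)) {
    needed <- c("concentrations", "expression", "map", "fractions", "mtx",
                "features", "barcodes", "cell_metadata", "ihc_regions")
    inp <- cfg$inputs
    if (is.null(inp)) {
      stop("configuration error: simulate is false but no 'inputs' block ",
           "was given", call. = FALSE)
    }
    miss_key <- setdiff(needed, names(inp))
    if (length(miss_key)) {
      stop("configuration error: missing input path(s): ",
           paste(miss_key, collapse = ", "), call. = FALSE)
    }
    for (k in needed) {
      if (!file.exists(inp[[k]])) {
        stop("input file not found: ", inp[[k]], " (", k, ")", call. = FALSE)
      }
    }
  }
  allowed_dialects <- c("inhouse", "zhang")
  d <- cfg$sc$dialect %||% "inhouse"
  if (!d %in% allowed_dialects) {
    stop("configuration error: sc.dialect must be one of ",
         paste(allowed_dialects, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# stderr logging keeps results streams clean
log_msg <- function(fmt, ...) {
  message(sprintf(paste0("[steroidscope] ", fmt), ...))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seed, "hash", x$config_hash, "\n")
  for (s in x$stages) {
    cat(sprintf("  %-10s %-4s %8.2fs  %s\n", s$name, s$status, s$elapsed_s,
                paste(s$outputs, collapse = ", ")))
  }
  invisible(x)
}
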