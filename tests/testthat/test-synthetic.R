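small_cfg <- function(seed = 1, ...) {
  cohort_config(seed = seed, n_patients = 6, n_steroids = 8,
                n_bulk_samples = 40, n_bulk_genes = 60, n_sc_genes = 200,
                n_cells_per_group = 50, n_ihc_regions_per_class = 4, ...)
}

test_that("the same config and seed reproduce the bundle exactly", {
  b1 <- generate_cohort(small_cfg(seed = 5))
  b2 <- generate_cohort(small_cfg(seed = 5))
  expect_identical(b1$concentrations, b2$concentrations)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$fractions, b2$fractions)
  expect_identical(as.matrix(b1$cells$counts), as.matrix(b2$cells$counts))
  expect_identical(b1$ihc_regions, b2$ihc_regions)
  # a different seed changes the data
  b3 <- generate_cohort(small_cfg(seed = 6))
  expect_false(identical(b1$concentrations, b3$concentrations))
})

test_that("components reproduce their values from the full bundle", {
  full <- generate_cohort(small_cfg(seed = 9))
  conc_only <- generate_cohort(small_cfg(seed = 9),
                               components = "concentrations")
  cells_only <- generate_cohort(small_cfg(seed = 9), components = "cells")
  expect_identical(conc_only$concentrations, full$concentrations)
  expect_identical(as.matrix(cells_only$cells$counts),
                   as.matrix(full$cells$counts))
})

test_that("generated fractions live on the simplex", {
  b <- generate_cohort(small_cfg(seed = 2), components = "fractions")
  expect_true(all(b$fractions >= 0 & b$fractions <= 1))
  expect_true(all(abs(rowSums(b$fractions) - 1) < 1e-9))
  expect_identical(colnames(b$fractions), steroidscope:::lm22_populations)
})

test_that("concentration marginals match the configured lognormal", {
  cfg <- cohort_config(seed = 13, n_patients = 10000, n_steroids = 3,
                       n_bulk_genes = 15, effect_conc = 0)
  b <- generate_cohort(cfg, components = "concentrations")
  meanlog <- b$ground_truth$conc_meanlog
  sdlog <- cfg$conc_sdlog
  for (s in rownames(b$concentrations)) {
    lx <- log(b$concentrations[s, ])
    # mean of log within 4 standard errors; sd within 5%
    expect_lt(abs(mean(lx) - meanlog[[s]]), 4 * sdlog / sqrt(10000))
    expect_lt(abs(sd(lx) - sdlog) / sdlog, 0.05)
  }
})

test_that("zero effect sizes leave no recoverable planted structure", {
  hits <- sapply(1:30, function(s) {
    cfg <- small_cfg(seed = 100 + s, effect_conc = 0, effect_producing = 0,
                     effect_receptor = 0, receptor_dominance = 0)
    b <- generate_cohort(cfg, components = c("concentrations", "expression"))
    sc <- steroid_overall_score(b$concentrations, b$expression, b$map)
    sc$steroid[sc$rank == 1L] == cfg$planted_steroid
  })
  # rank-1 frequency should be consistent with 1/8 under the null
  expect_lt(sum(hits), qbinom(0.999, 30, 1 / 8) + 1)
})

test_that("ground truth records the planted parameters", {
  b <- generate_cohort(small_cfg(seed = 3))
  gt <- b$ground_truth
  expect_identical(gt$planted_steroid, "cortisol")
  expect_identical(gt$planted_receptor, "CORTISOL_RC1")
  expect_true(gt$planted_receptor %in% rownames(b$expression))
  expect_true(all(gt$signature_genes %in% rownames(b$cells$counts)))
  expect_identical(gt$seed, 3L)
})

test_that("bundles round-trip through the on-disk formats", {
  b <- generate_cohort(small_cfg(seed = 4))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_bundle(dir)
  expect_identical(back$concentrations, {
    x <- b$concentrations
    attr(x, "meanlog") <- NULL
    x
  })
  expect_identical(back$expression, b$expression)
  expect_identical(back$fractions, b$fractions)
  expect_equal(back$map, b$map)
  expect_identical(as.matrix(back$cells$counts), as.matrix(b$cells$counts))
  expect_equal(back$cells$meta, b$cells$meta)
  expect_equal(tibble::as_tibble(back$ihc_regions), b$ihc_regions)
  expect_identical(back$ground_truth$planted_steroid,
                   b$ground_truth$planted_steroid)
})

test_that("an empty cell component writes a valid, re-readable MTX", {
  b <- generate_cohort(small_cfg(seed = 8))
  # zero cells: degenerate but well-formed
  empty <- cell_matrix(b$cells$counts[, 0, drop = FALSE],
                       group = character(0))
  dir <- withr::local_tempdir()
  write_sparse_counts(empty, dir)
  back <- read_sparse_counts(file.path(dir, "counts.mtx"),
                             file.path(dir, "features.tsv"),
                             file.path(dir, "barcodes.tsv"))
  expect_identical(dim(back$counts), c(200L, 0L))
})

test_that("unusable output directories surface an IO error with the path", {
  b <- generate_cohort(small_cfg(seed = 8),
                       components = "concentrations")
  blocked <- withr::local_tempfile()
  writeLines("not a directory", blocked) # a file squatting on the dir path
  expect_error(write_bundle(b, blocked), "cannot create output directory")
})
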