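test_that("QC dialects encode the documented inequalities", {
  # one representative cell per regime, checked against both dialects
  meta_cases <- tibble::tribble(
    ~n_genes, ~n_umi, ~pct_mito, ~inhouse, ~zhang,
    300L, 5000L, 5, TRUE, FALSE, # zhang gene floor is 400
    100L, 5000L, 5, FALSE, FALSE, # below both gene floors
    200L, 5000L, 5, FALSE, FALSE, # inhouse bound is strict (> 200)
    400L, 5000L, 5, TRUE, TRUE, # zhang floor is inclusive
    7500L, 50000L, 5, FALSE, TRUE, # inhouse cap strict (< 7500)
    500L, 60000L, 5, FALSE, TRUE, # inhouse UMI cap strict (< 60000)
    500L, 500L, 5, TRUE, FALSE, # zhang UMI floor 600
    500L, 5000L, 20, TRUE, FALSE, # inhouse keeps exactly 20% mito
    500L, 5000L, 20.5, FALSE, FALSE
  )
  for (dialect in c("inhouse", "zhang")) {
    th <- qc_thresholds(dialect)
    inc <- th$inclusive
    keep <- mapply(function(g, u, m) {
      gl <- if (inc[["genes_lo"]]) g >= th$min_genes else g > th$min_genes
      gh <- if (inc[["genes_hi"]]) g <= th$max_genes else g < th$max_genes
      ul <- if (inc[["umi_lo"]]) u >= th$min_umi else u > th$min_umi
      uh <- if (inc[["umi_hi"]]) u <= th$max_umi else u < th$max_umi
      mt <- if (inc[["mito"]]) m <= th$max_pct_mito else m < th$max_pct_mito
      gl && gh && ul && uh && mt
    }, meta_cases$n_genes, meta_cases$n_umi, meta_cases$pct_mito)
    expect_identical(unname(keep), meta_cases[[dialect]])
  }
  expect_error(qc_thresholds(min_genes = 500, max_genes = 100),
               "below upper")
  expect_error(qc_thresholds(min_genes = 1, max_genes = 10,
                             max_pct_mito = 150), "0, 100")
})

test_that("qc_filter matches brute-force per-cell evaluation", {
  b <- generate_cohort(cohort_config(seed = 21, n_cells_per_group = 150,
                                     n_sc_genes = 300),
                       components = "cells")
  # thresholds placed inside the realistic covariate range of this cohort
  th <- qc_thresholds(min_genes = 60, max_genes = 200, min_umi = 100,
                      max_umi = 600, max_pct_mito = 8)
  res <- qc_filter(b$cells, th)
  m <- b$cells$meta
  brute <- m$n_genes >= 60 & m$n_genes <= 200 & m$n_umi >= 100 &
    m$n_umi <= 600 & m$pct_mito <= 8
  expect_identical(res$keep, brute)
  expect_identical(colnames(res$cells$counts), m$barcode[brute])
  expect_identical(res$report$n_removed[res$report$criterion == "any"],
                   sum(!brute))
  # per-criterion counts
  expect_identical(
    res$report$n_removed[res$report$criterion == "mito"],
    sum(m$pct_mito > 8))
})

test_that("qc_filter of an empty matrix returns an empty, zero-count report", {
  empty <- cell_matrix(Matrix::Matrix(0L, 0, 0, sparse = TRUE,
                                      dimnames = list(character(), character())))
  res <- qc_filter(empty, qc_thresholds("inhouse"))
  expect_identical(ncol(res$cells$counts), 0L)
  expect_true(all(res$report$n_removed == 0L))
})

test_that("log_normalize equals the dense CP10K formula", {
  counts <- random_counts(30, 12, seed = 9, lambda = 3)
  cells <- make_cells(counts)
  norm <- log_normalize(cells)
  dense <- as.matrix(norm)
  totals <- colSums(counts)
  expected <- log1p(sweep(counts, 2, totals, function(c, t) c * 1e4 / t))
  expect_equal(dense, expected, tolerance = 1e-12)
  # spot values from direct evaluation of the formula
  one <- log_normalize(make_cells(matrix(c(10, 990), 2, 1,
                                         dimnames = list(c("a", "b"), "c1"))))
  expect_equal(one["a", "c1"], log(101))
  expect_equal(as.numeric(log1p(1 * 1e4 / 1e4)), log(2)) # unit-count check
  # zeros stay zero (sparsity preserved)
  expect_identical(Matrix::nnzero(norm), Matrix::nnzero(cells$counts))

  zero_cell <- matrix(c(1, 0, 2, 0), 2, 2,
                      dimnames = list(c("a", "b"), c("ok", "empty")))
  zero_cell[, 2] <- 0
  expect_error(log_normalize(make_cells(zero_cell)), "empty")
})

test_that("module score is zero under flat expression and exact on one bin", {
  # identical expression everywhere: set mean == control mean by symmetry
  flat <- matrix(1, 20, 6, dimnames = list(sprintf("g%02d", 1:20),
                                           sprintf("c%d", 1:6)))
  ms <- module_score(flat, c("g01", "g02"), n_bins = 1, n_ctrl = 5, seed = 1)
  expect_equal(ms$score, rep(0, 6))

  # one bin, n_ctrl = all non-set genes: score = mean(set) - mean(non-set)
  withr::with_seed(31, {
    x <- matrix(rexp(6 * 4), 6, 4,
                dimnames = list(paste0("g", 1:6), paste0("c", 1:4)))
  })
  set <- c("g1", "g2")
  ms2 <- module_score(x, set, n_bins = 1, n_ctrl = 4, seed = 2)
  brute <- colMeans(x[set, ]) - colMeans(x[setdiff(rownames(x), set), ])
  expect_equal(ms2$score, unname(brute))

  # determinism under a fixed seed
  ms3 <- module_score(x, set, n_bins = 1, n_ctrl = 4, seed = 2)
  expect_identical(ms2$score, ms3$score)

  expect_error(module_score(x, "absent_gene", n_bins = 1), "absent_gene")
  expect_error(module_score(x, set, n_bins = 100), "n_bins")
})

test_that("module score of a random gene set is centred near zero", {
  b <- generate_cohort(cohort_config(seed = 41, n_cells_per_group = 100,
                                     n_sc_genes = 500, signature_delta = 0),
                       components = "cells")
  norm <- log_normalize(b$cells)
  pool <- setdiff(rownames(norm), b$signature_genes)
  means <- withr::with_seed(5, {
    sapply(1:100, function(s) {
      gs <- sample(pool, 20)
      mean(module_score(norm, gs, seed = s)$score)
    })
  })
  # null distribution of per-seed mean scores should straddle zero
  expect_lt(abs(mean(means)), 2 * sd(means) / sqrt(length(means)) + 1e-3)
})

test_that("group comparison reproduces the hand Welch computation", {
  same <- compare_groups(c(1, 2, 3, 1, 2, 3),
                         factor(rep(c("a", "b"), each = 3)))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  cmp <- compare_groups(c(1, 2, 3, 4, 5, 6),
                        factor(rep(c("g1", "g2"), each = 3)))
  expect_equal(cmp$t_statistic, -3.674235, tolerance = 1e-6)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p_value, 0.0213, tolerance = 1e-3)

  withr::with_seed(51, {
    a <- rnorm(15)
    b <- rnorm(20, mean = 0.4, sd = 2)
  })
  got <- compare_groups(c(a, b), factor(rep(c("a", "b"), c(15, 20))))
  want <- oracle_welch(a, b)
  expect_equal(got$t_statistic, want$t)
  expect_equal(got$df, want$df)
  expect_equal(got$p_value, want$p)
  expect_equal(got$mean_diff, mean(a) - mean(b))

  expect_error(compare_groups(1:4, factor(c("a", "b", "b", "b"))),
               "at least 2")
  expect_error(compare_groups(1:4, factor(rep("a", 4))), "two groups")
})
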