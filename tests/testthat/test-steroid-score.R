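test_that("zscore follows the sample-sd convention and propagates NA", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(zscore(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(zscore(c(1, 2, NA, 3)), c(-1, 0, NA, 1))
  expect_equal(zscore(7), 0) # single value: degenerate, maps to zero
  expect_error(zscore(numeric(0)), "empty")
})

test_that("z-vectors have mean 0 and sample sd 1 on random inputs", {
  withr::with_seed(101, {
    for (i in 1:100) {
      n <- sample(2:50, 1)
      x <- rnorm(n) * 10^sample(-2:3, 1)
      if (sd(x) == 0) next
      z <- zscore(x)
      expect_lt(abs(mean(z)), 1e-10)
      expect_lt(abs(sd(z) - 1), 1e-10)
    }
  })
})

test_that("layer summaries average the right slices", {
  # concentration layer: plain mean over patients, optional log10
  conc <- matrix(c(2, 4), 1, 2, dimnames = list("cortisol", c("p1", "p2")))
  expect_equal(unname(layer_summary(conc, layer = "concentration",
                                    log_conc = FALSE)), 3)
  expect_equal(unname(layer_summary(conc, layer = "concentration",
                                    log_conc = TRUE, conc_floor = 0)),
               mean(log10(c(2, 4))))

  # gene layer: grand mean over mapped genes x samples
  expr <- matrix(c(1, 3, 5, 7), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("s1", "s2")))
  map <- steroid_gene_map("x", producing = list(c("A", "B")),
                          receptor = list(character(0)))
  expect_equal(unname(layer_summary(expr, map, "producing")), 4,
               ignore_attr = TRUE)
  # empty receptor list -> NA, and an all-NA layer errors
  map2 <- steroid_gene_map(c("x", "y"),
                           producing = list("A", "B"),
                           receptor = list(character(0), "A"))
  expect_equal(unname(layer_summary(expr, map2, "receptor")), c(NA, 2),
               ignore_attr = TRUE)
  map3 <- steroid_gene_map("x", producing = list("NOT_THERE"),
                           receptor = list(character(0)))
  expect_error(layer_summary(expr, map3, "producing"), "NOT_THERE")
})

test_that("gene matching is case-insensitive and whitespace-tolerant", {
  expr <- matrix(1:4, 2, 2,
                 dimnames = list(c("Nr3c1", "AR"), c("s1", "s2")))
  map <- steroid_gene_map("cortisol", producing = list(" NR3C1 "),
                          receptor = list("ar"))
  expect_equal(unname(layer_summary(expr, map, "producing")), mean(c(1, 3)),
               ignore_attr = TRUE)
  expect_equal(unname(layer_summary(expr, map, "receptor")), mean(c(2, 4)),
               ignore_attr = TRUE)
})

make_two_steroid_inputs <- function(conc_means = c(10, 1),
                                    prod_means = c(5, 1),
                                    rec_means = c(4, 2)) {
  map <- tiny_map()
  conc <- matrix(rep(conc_means, each = 2), 2, 2, byrow = TRUE,
                 dimnames = list(map$steroid, c("p1", "p2")))
  genes <- c("CYP11B1", "HSD11B1", "HSD17B3", "NR3C1", "AR")
  expr <- matrix(c(prod_means[1], prod_means[1], prod_means[2],
                   rec_means[1], rec_means[2]),
                 nrow = 5, ncol = 3, dimnames = list(genes, paste0("s", 1:3)))
  list(conc = conc, expr = expr, map = map)
}

test_that("overall score composes layer z-scores and ranks deterministically", {
  inp <- make_two_steroid_inputs()
  s <- steroid_overall_score(inp$conc, inp$expr, inp$map, log_conc = FALSE)
  # two steroids, sample sd: each layer z is +/- 1/sqrt(2)
  z <- 1 / sqrt(2)
  expect_equal(s$z_conc, c(z, -z))
  expect_equal(s$z_producing, c(z, -z))
  expect_equal(s$z_receptor, c(z, -z))
  expect_equal(s$overall_score, c(z, -z))
  expect_identical(s$rank, c(1L, 2L))
  expect_identical(s$steroid, c("cortisol", "testosterone"))
})

test_that("constant layers give all-zero scores with lexicographic tie rank", {
  inp <- make_two_steroid_inputs(conc_means = c(3, 3), prod_means = c(2, 2),
                                 rec_means = c(4, 4))
  s <- steroid_overall_score(inp$conc, inp$expr, inp$map, log_conc = FALSE)
  expect_equal(s$overall_score, c(0, 0))
  expect_identical(s$steroid[s$rank == 1L], "cortisol") # "c" < "t"
})

test_that("missing layers are averaged over the available z-scores", {
  inp <- make_two_steroid_inputs()
  # strip the receptor genes for both steroids -> receptor layer all NA
  map <- steroid_gene_map(inp$map$steroid,
                          producing = inp$map$producing,
                          receptor = list(character(0), character(0)))
  expect_warning(
    s <- steroid_overall_score(inp$conc, inp$expr, map, log_conc = FALSE),
    "receptor")
  z <- 1 / sqrt(2)
  expect_equal(s$overall_score, c(z, -z)) # mean of the two available layers

  # one steroid missing one layer: its overall is the mean of what it has
  map2 <- steroid_gene_map(inp$map$steroid,
                           producing = inp$map$producing,
                           receptor = list("NR3C1", character(0)))
  s2 <- steroid_overall_score(inp$conc, inp$expr, map2, log_conc = FALSE)
  row <- s2[s2$steroid == "testosterone", ]
  expect_true(is.na(row$z_receptor))
  expect_equal(row$overall_score, mean(c(row$z_conc, row$z_producing)))
})

test_that("overall score requires two shared steroids", {
  inp <- make_two_steroid_inputs()
  conc1 <- inp$conc["cortisol", , drop = FALSE]
  expect_error(steroid_overall_score(conc1, inp$expr, inp$map),
               "at least two steroids")
})

test_that("overall score is invariant to affine rescaling of a layer", {
  withr::with_seed(7, {
    b <- generate_cohort(cohort_config(seed = 7, n_steroids = 10,
                                       n_bulk_samples = 20,
                                       n_bulk_genes = 60),
                         components = c("concentrations", "expression"))
  })
  s0 <- steroid_overall_score(b$concentrations, b$expression, b$map,
                              log_conc = FALSE)
  # affine rescale of the whole expression layer: z-scores unchanged
  s1 <- steroid_overall_score(b$concentrations, 3.7 * b$expression + 11,
                              b$map, log_conc = FALSE)
  expect_equal(s1$overall_score, s0$overall_score, tolerance = 1e-9)
  expect_identical(s1$rank, s0$rank)
})

test_that("permuting steroid order permutes the score table identically", {
  withr::with_seed(8, {
    b <- generate_cohort(cohort_config(seed = 8, n_steroids = 8,
                                       n_bulk_samples = 15,
                                       n_bulk_genes = 50),
                         components = c("concentrations", "expression"))
  })
  s0 <- steroid_overall_score(b$concentrations, b$expression, b$map)
  perm <- withr::with_seed(1, sample(nrow(b$concentrations)))
  map_perm <- b$map[perm, ]
  conc_perm <- b$concentrations[perm, ]
  s1 <- steroid_overall_score(conc_perm, b$expression, map_perm)
  expect_equal(s1[order(s1$steroid), ], s0[order(s0$steroid), ],
               ignore_attr = TRUE)
})
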