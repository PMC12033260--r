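# Independent oracles used across the suite. These are deliberately naive
# (loops, textbook formulas) and share no code with the implementation.

# product-moment correlation + two-sided t-based p, written out longhand
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  r <- sxy / sqrt(sxx * syy)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# textbook BH step-up: sort, scale by m/i, cummin from the largest, cap at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- (m / seq_len(m)) * p[o] # m/i first: matches IEEE rounding order
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Welch two-sample t-test from the definition
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df = df))
}

# tiny deterministic cell_matrix built from a dense integer matrix
make_cells <- function(counts, group = NULL) {
  steroidscope::cell_matrix(Matrix::Matrix(counts, sparse = TRUE),
                            group = group)
}

random_counts <- function(n_genes, n_cells, seed, mito_frac = 0.1,
                          lambda = 2) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells)
    n_mito <- max(1L, round(mito_frac * n_genes))
    rn <- c(sprintf("MT-G%02d", seq_len(n_mito)),
            sprintf("GENE%04d", seq_len(n_genes - n_mito)))
    dimnames(m) <- list(rn, sprintf("cell_%04d", seq_len(n_cells)))
    m
  })
}

tiny_map <- function() {
  steroidscope::steroid_gene_map(
    steroid = c("cortisol", "testosterone"),
    producing = list(c("CYP11B1", "HSD11B1"), c("HSD17B3")),
    receptor = list(c("NR3C1"), c("AR"))
  )
}
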