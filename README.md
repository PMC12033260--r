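# steroidscope

Integrative steroid–immune profiling of the tumour microenvironment.

Tumour-infiltrating immune cells can synthesise steroids locally
(CYP11A1-driven de novo steroidogenesis), and the steroids produced —
glucocorticoids in particular — suppress anti-tumour immunity in
triple-negative breast cancer (TNBC). `steroidscope` is an R package for
the computational side of that biology, aimed at analysts combining
targeted steroid metabolomics with bulk and single-cell transcriptomics:

* **Integrative steroid score** — for each steroid $s$, three evidence
  layers are summarised (mean tissue concentration $c_s$, mean expression
  of producing-enzyme genes $p_s$, mean expression of receptor genes
  $r_s$), each layer is z-scored across steroids, and the overall score is
  the row mean $\mathrm{score}_s = \mathrm{mean}(z_c, z_p, z_r)$. Ranking
  the scores identifies the dominant steroid axis in the tissue.
* **Receptor / immune-fraction screen** — Pearson correlation of every
  steroid-receptor gene against every deconvolved immune-population
  fraction (LM22-style input), two-sided p-values, Benjamini–Hochberg FDR.
* **Single-cell stage** — QC filtering (two published threshold dialects),
  counts-per-10k log-normalization $\ln(1 + 10^4 c/T)$, control-gene-binned
  gene-set module scoring, and Welch t-tests between cell groups.
* **LC-MS calibration** — OLS calibration curves and inverse prediction of
  steroid amounts from peak-area ratios.
* **IHC & preclinical utilities** — H-score ($I \times P$, 0–300),
  region-class comparison, tumour volume and burden checks.
* **Synthetic cohort generator** — a seeded multi-omics cohort with
  planted, recoverable effects, so the whole pipeline is testable with no
  external data.

## Worked example

```r
library(steroidscope)

cohort <- generate_cohort(cohort_config(seed = 42))
scores <- steroid_overall_score(cohort$concentrations,
                                cohort$expression, cohort$map)
head(scores, 3)
#> # A tibble: 3 × 9
#>   steroid    mean_conc mean_producing mean_receptor z_conc z_producing z_receptor
#> 1 cortisol        1.15           4.60          6.88   1.24       2.26      4.17
#> 2 11-deoxy…       1.46           4.00          2.80   1.80       1.35     -0.518
#> 3 estriol         1.31           4.09          2.39   1.53       1.49     -0.983
```

Cortisol ranks first: its concentration, producing-enzyme expression and
receptor expression are all elevated, and the mean of the three layer
z-scores (2.56) dominates the panel. `autoplot(scores)` draws the ranked
bar chart.

```r
screen <- receptor_immune_screen(cohort$expression, cohort$fractions,
                                 genes = "CORTISOL_RC1")
dplyr::arrange(screen, p_adjusted)
#>   gene         population                     r  p_value n_samples p_adjusted
#> 1 CORTISOL_RC1 Macrophages M2             0.527 3.85e-27       360   1.69e-25
#> 2 CORTISOL_RC1 Macrophages M1            -0.376 1.59e-13       360   3.50e-12
#> 3 CORTISOL_RC1 Dendritic cells activated -0.362 1.47e-12       360   2.15e-11
```

The glucocorticoid receptor correlates positively with M2 macrophage
fractions and negatively with M1 macrophages and activated dendritic
cells — the immunosuppressive pattern the screen is designed to expose.

```r
qc   <- qc_filter(cohort$cells, qc_thresholds("inhouse"))   # 390/400 kept
norm <- log_normalize(qc$cells)                             # CP10K
ms   <- module_score(norm, cohort$signature_genes, seed = 42)
compare_groups(ms$score, factor(qc$cells$meta$group,
                                levels = c("tumour", "blood")))
#>   group1 group2 mean1  mean2 mean_diff t_statistic    df  p_value method
#> 1 tumour blood  0.194 -0.217     0.411        12.9  388. 5.70e-32 welch
```

Tumour-derived immune cells score 0.41 log-normalized units higher on the
steroid-biosynthesis signature than blood-derived cells (Welch p ≈ 6e-32):
the planted enrichment is recovered.

One call runs every stage and writes TSV/JSON outputs plus a manifest:

```r
run_pipeline(list(seed = 1, out_dir = "results/run1", simulate = TRUE))
```

A thin CLI wrapper with `run`, `simulate`, `score`, `correlate`,
`sc-score`, `ihc` and `tumour` subcommands is installed at
`system.file("cli", "steroidscope", package = "steroidscope")`.

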