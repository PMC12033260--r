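---
title: "Methods: integrative steroid-immune profiling with steroidscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative steroid-immune profiling with steroidscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steroidscope)
```

## The scientific problem

Solid tumours — triple-negative breast cancer (TNBC) in particular — can
harbour local steroidogenesis: tumour-infiltrating immune cells express
CYP11A1, the rate-limiting cholesterol side-chain-cleavage enzyme, and the
steroids produced (glucocorticoids above all) push dendritic cells towards
tolerance, macrophages towards an M2 phenotype, and CD8+ T cells towards
exhaustion. Asking *which* steroid dominates a tumour's microenvironment
requires combining evidence that no single assay provides: tissue steroid
concentrations (targeted LC-MS/MS), expression of each steroid's
biosynthetic enzymes, and expression of its receptors. `steroidscope`
implements that integration, plus the surrounding analysis stages, as a
tested pipeline that can be exercised end to end on a synthetic cohort with
known planted effects.

## The integrative steroid score

For steroid $s$ the score combines three evidence layers:

* $c_s$ — mean across patients of the (log10-transformed) tissue
  concentration of $s$, in ng/g;
* $p_s$ — mean expression of the genes encoding the enzymes that *produce*
  $s$ (grand mean over genes and samples);
* $r_s$ — mean expression of the genes encoding the *receptors* of $s$.

Each layer vector is z-scored **across steroids** (sample standard
deviation, ddof = 1), and the overall score is the row mean of the
available layer z-scores:

$$\mathrm{score}_s = \tfrac{1}{|L_s|}\sum_{\ell \in L_s} z_\ell(s),
\qquad L_s \subseteq \{c, p, r\}.$$

Steroids are ranked by descending score; ties break lexicographically on
the steroid label so output is deterministic.

**Why z across steroids, not across patients.** "Z-score each layer" is
ambiguous: standardising each steroid's concentrations across patients
would centre every steroid at zero and make between-steroid ranking
impossible. We therefore average over patients/samples first and
standardise the resulting per-steroid vectors across steroids, which
yields exactly one comparable bar per steroid. This is the single most
consequential interpretation made in the package. The alternative —
z-scoring across steroids *within* every patient/sample and averaging the
z-scores afterwards — is exposed as `per_sample_z = TRUE` in
`steroid_overall_score()`; on the synthetic cohorts the two orderings
agree closely, but average-then-z is the primary formulation.

**Other choices.**

* Concentrations are log10-transformed with a pseudo-floor of 1e-3 ng/g
  before averaging (`log_conc`, `conc_floor`): tissue steroid
  concentrations span orders of magnitude, and without the log a single
  abundant steroid's patient-level noise dominates its layer mean. The
  floor keeps true zeros finite and is negligible for measurable
  concentrations.
* Layers are weighted equally; a steroid missing a layer (e.g. no known
  receptor gene, as for pregnenolone) is scored on the mean of the layers
  it has, and an entirely absent layer is dropped with a warning.
* Gene symbols are matched case-insensitively after trimming whitespace;
  unmatched map genes are reported, not fatal.
* Zero-variance or single-value layers z-score to all zeros rather than
  NaN, so a degenerate layer contributes nothing instead of poisoning the
  mean.
* The steroid-to-gene map is data, not code: a small KEGG-style default
  for the major steroid classes ships in
  `inst/extdata/steroid_gene_map.json` and is fully editable.

## Calibration-curve quantification

LC-MS/MS steroid amounts are quantified by ordinary least squares of the
analyte / internal-standard peak-area ratio on the known calibration
amounts, inverted for unknowns:
$\hat a = (\text{ratio} - \beta_0)/\beta_1$. Sub-zero inverse predictions
(signals below the blank) are returned as-is with a `below_zero` flag so
the caller decides whether to clamp or censor them. A degenerate design
(all calibration amounts equal) is an error, not a silent NA.

## Receptor / immune-fraction correlation screen

Immune-population fractions (an LM22-style deconvolution output,
samples × populations on the simplex) are consumed as input — the package
does not perform deconvolution. For each (receptor gene, population) pair
the screen computes the Pearson correlation across the shared samples,
with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, pairwise-complete
NA handling, and per-row $n$ reported. Perfect correlations carry the
limiting p-value, clamped to the smallest positive double so the family
stays in (0, 1].

Multiplicity is controlled by Benjamini–Hochberg step-up. The source
analysis says only that p-values were adjusted; BH is the field's default
for screens of this shape and is what we adopt. The family is the whole
gene × population table by default (`adjust = "table"`); per-gene families
are available via `adjust = "per_gene"`. Two-sided tests throughout.

## Single-cell stage

**QC filtering.** Two threshold dialects are shipped verbatim, matching
the filtering rules used for in-house 10x data and for the public TNBC
tumour/blood atlas respectively:

| bound | `inhouse` | `zhang` |
|---|---|---|
| detected genes | > 200 and < 7,500 (strict) | 400–8,000 (inclusive) |
| UMI count | < 60,000 (strict) | 600–120,000 (inclusive) |
| mitochondrial % | kept if ≤ 20 | kept if ≤ 10 |

Strict versus inclusive bounds follow the wording of each rule ("greater
than", "below", "more than ... discarded"). Per-cell covariates are always
recomputed from the count matrix and a mitochondrial-prefix rule (default
`MT-`/`mt-`; the rule is configurable because the annotation convention is
dataset-dependent), so metadata can never drift from the matrix.

**Normalization.** Counts-per-10k log-normalization,
$\ln(1 + c \cdot 10{,}000 / T)$ per entry with $T$ the cell total. Zeros
map to zero, so the sparse structure is preserved; zero-total cells are an
error naming the barcode.

**Module scoring.** Gene-set activity per cell is scored against
expression-matched controls, in the style of Seurat's `AddModuleScore`
defaults: genes are ranked by average normalized expression and divided
into `n_bins = 24` equal-frequency bins (ties broken by stable gene
order); for each set gene, `n_ctrl = 100` control genes are drawn from its
bin — excluding gene-set members, without replacement when the bin is
large enough, with replacement otherwise; the score is
mean(set) − mean(pooled controls) per cell. Drawing controls from the same
average-expression bin removes the depth/abundance component of the score,
so a random gene set is centred at zero by construction (a property the
test suite checks over 100 seeds). All draws flow from one documented
seed, recorded in the result.

**Group comparison.** Scores are compared between tumour- and
blood-derived cells by an unpaired two-sided t-test. We default to the
Welch unequal-variance form — the safer choice when group variances are
not known to be equal — with the classical Student form available via
`var_equal = TRUE`.

## IHC and preclinical utilities

The H-score is intensity (0–3) × positive percentage (0–100), range
0–300. Percentage may be recorded as a raw number or as a 10-point
category code; `ihc_category_to_percent()` maps category $k \ge 1$ to its
interval midpoint $10k - 5$ (and 0 to 0), since the underlying percentage
is unrecoverable from the code. Region-level steroidogenic activity is
contrasted between immune-infiltrated regions and the rest by the same
Welch test.

Tumour volume uses the convention $(\pi/6)(\text{shortest} \times
\text{longest})$ **verbatim**. Note this lacks the squared term of the
common ellipsoid approximation $L \times W^2 / 2$ and is therefore
quadratic rather than cubic in length; we implement the formula as stated
rather than silently "correcting" it, and document the discrepancy here.
The tumour-burden rule is $(\text{shortest} + \text{longest})/2 \le 15$ mm
with an inclusive boundary.

## The synthetic cohort generator

`generate_cohort()` emulates all six pipeline inputs with planted,
recorded effects. Its defaults *are* the study conditions: 16 patients ×
31 steroids, 360 bulk samples, 22 immune populations, 200 cells per group,
planted three-layer elevation of cortisol, a dominant receptor gene, a
signed receptor↔fraction correlation pattern, and a 25-gene signature
boosted by 0.5 log-units in tumour cells.

* **Concentrations** are lognormal: per-steroid location drawn once from
  Normal(1, 1) (natural-log ng/g scale, i.e. a few ng/g in the median),
  σ = 0.8 across patients; the planted steroid's location is shifted up by
  `effect_conc = 2` log-units. With 31 steroids the between-steroid
  location spread is ~1, so a 2-log-unit shift puts the planted steroid
  ~2 sd above the pack in its layer — large enough to be recovered
  reliably when averaged over three layers, small enough that single
  layers overlap.
* **Bulk expression** is Gaussian on the log scale: gene baselines
  Normal(3, 1), sample noise sd 1. The planted steroid's three producing
  and two receptor genes get +2 log-units; its first receptor gene a
  further +1 (`receptor_dominance`), mirroring one clearly dominant
  receptor.
* **Fractions** are Dirichlet on the simplex (total concentration 100,
  moderately uneven base composition). Planted populations' concentrations
  are modulated log-linearly by the standardized expression of the planted
  receptor, $\alpha_{ik} = \alpha^0_k \exp(s_k\, w\, x_i)$, which plants
  signed, noisy correlations. The weight `cor_strength = 0.2` was
  calibrated once so the realised planted correlations average
  $|r| \approx 0.4$ at $n = 360$.
* **Single-cell counts** are negative binomial (size 2) with lognormal
  per-gene means (meanlog log 0.3, sdlog 1 — the right-skewed mean
  distribution of droplet data), 13 mitochondrial genes at higher means
  (~5% mitochondrial content), per-cell library factors lognormal(0, 0.3),
  and the signature set multiplied by $e^{0.5}$ in tumour cells.
* **IHC regions** draw immune-infiltrated regions from intensity {2, 3}
  and 60–95% positivity; tumour/stroma regions from intensity {0, 1, 2}
  and 5–40%.

All randomness flows from the single config seed through per-component
sub-seeds, so generating any subset of components reproduces exactly the
values it would have inside the full bundle, and the same config + seed is
bit-reproducible.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: LC-MS peak shapes and limits of
quantification, doublets and ambient RNA, batch effects, compositional
coupling between bulk expression and the deconvolved fractions beyond the
planted pairs, spatial structure in IHC, and any real covariance between
steroids sharing a biosynthetic pathway. Recovery results certify the
*statistical machinery*, not biological claims.

## Problem sizes and runtime choices

The recovery properties are evaluated over 100 independent seeds at the
default cohort dimensions: planted-steroid rank-1 recovery and its null
(effect 0) counterpart; sign recovery of the planted correlation pairs
(screened against a 5-receptor panel, which keeps the 100-seed loop fast
while preserving a realistic BH family); and module-score enrichment
detection at Δ = 0.5 with a Δ = 0 calibration check of the type-I error.
These sizes give binomial standard errors of ~2–5 percentage points on the
reported rates and run in well under a minute each on one core.

## Numerical conventions

* Sample (ddof = 1) standard deviation everywhere a z-score is formed.
* Zero-variance z-scores are defined as 0; empty vectors are errors.
* Rank ties break lexicographically on the steroid label.
* BH adjustment is `stats::p.adjust(method = "BH")`; the test suite
  verifies it against an independent sort/step-up/cummin implementation.
* TSV round-trips use shortest round-trip ("grisu") double formatting, so
  written matrices re-read bit-identically and pipeline reruns with the
  same seed are byte-stable.

## Known limitations

* The integration score treats layers as exchangeable evidence; no
  weighting or uncertainty propagation between layers is attempted.
* The correlation screen is marginal Pearson: fraction compositionality
  (simplex constraint) and confounding between populations are ignored,
  as in the screen it reproduces.
* Module scores depend on the binning granularity for very small
  matrices; `n_bins` must not exceed the gene count, and with few genes
  the control matching is coarse.
* The tumour-volume convention is dimensionally odd (see above); use
  `tumour_metrics()` output accordingly.
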