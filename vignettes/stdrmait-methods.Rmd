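---
title: "Methods: weighted mixed-model single-cell DE and compositional microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted mixed-model single-cell DE and compositional microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdrmait)
```

# Scope

`stdrmait` implements the statistical machinery for a repeated-measures
dietary-restriction study of circulating mucosal-associated invariant T
(MAIT) cells: seven subjects sampled at baseline, on days 2 and 4 of a
protein–calorie-restricted diet, and on day 7 after refeeding, with 10x
droplet scRNA-seq of PBMCs at every blood draw and shotgun stool
metagenomics at baseline, day 4 and day 7. The package covers four stages —
cell QC and marker gating, per-gene weighted linear mixed-model differential
expression, gene-set enrichment with directional activation scores, and
compositional microbiome differential abundance — plus a synthetic-data
generator that emulates the sampling design so every stage can be exercised
and benchmarked against known truth without any external data.

# The differential-expression model

For gene $g$, subject $i$, cell $j$, the response is log-normalized
expression $y_{ijg} = \ln(1 + 10^4\, c_{ijg}/N_{ij})$ and the model is

$$y_{ijg} = \beta_0 + \beta_1\,\mathrm{day2}_{ij} + \beta_2\,\mathrm{day4}_{ij}
          + \beta_3\,\mathrm{day7}_{ij} + \alpha_i + \varepsilon_{ijg},$$

with $\alpha_i \sim N(0, \tau^2)$ a random subject intercept and
$\varepsilon_{ijg} \sim N(0, \sigma_g^2/\omega_{ijg})$. Time points enter as
dummy indicators against the baseline, so $\beta_1,\beta_2,\beta_3$ are the
mean log-expression changes of each diet day relative to baseline
("LogFc"), shared across subjects, while the subject intercept absorbs the
repeated-measures correlation among a subject's cells.

The observation weight is multiplicative, $\omega = \omega^{\mathrm{voom}}
\cdot \omega^{\mathrm{zinb}}$:

* **voom precision weights** (`compute_voom_weights()`, via limma): log-CPM
  with prior count 0.5, a lowess trend of $\sqrt{\mathrm{sd}}$ against
  average log-count across genes, and per-observation weight equal to the
  trend-predicted standard deviation$^{-4}$ at the fitted log-count. This
  encodes the count mean–variance relationship so that ordinary linear-model
  machinery applies to the log scale.
* **ZINB dropout weights** (`fit_zinb_gene()`, `compute_zinb_weights()`): an
  intercept-only zero-inflated negative binomial is fitted per gene by
  direct maximum likelihood (box-constrained quasi-Newton with analytic
  gradients; NB parameterised by mean $\mu$ and size $k$, with log
  library-size offsets). A positive count gets weight 1; a zero is weighted
  by the posterior probability that it arose from the NB component,
  $(1-\pi) f_{NB}(0) / (\pi + (1-\pi) f_{NB}(0)) \in (0,1]$, so likely
  technical dropouts barely influence the fit.

## REML fitting

`fit_weighted_lmm()` estimates $(\beta, \tau^2, \sigma_g^2)$ by REML. With a
single random intercept the covariance is
$\sigma^2(W^{-1} + \lambda ZZ^\top)$ with $\lambda = \tau^2/\sigma^2$, and
per-subject Woodbury identities reduce each REML evaluation to
$O(\text{subjects})$ after one $O(\text{cells})$ pass. The profiled
criterion is minimised over $\log\lambda \in [-15, 10]$ by golden-section
search and compared against the $\lambda = 0$ boundary, so the fit cannot
converge to a negative variance and never fails to terminate. The solver
agrees with `lme4::lmer` (weights, REML) to ~5 decimals on heteroscedastic
grouped data and reduces exactly to (weighted) least squares when
$\lambda = 0$; the tests assert both.

Residual degrees of freedom are taken as $n - p - (S - 1)$, treating the $S$
subject effects as absorbing one degree of freedom each beyond the grand
intercept; with ~1400 cells the moderation result is insensitive to this
choice.

## Moderation, FDR and DEG calls

`moderate_statistics()` shrinks per-gene variances with the scaled
inverse-chi-square prior of the limma framework, estimating $(d_0, s_0^2)$
by closed-form method of moments on $\log s_g^2$ (digamma/trigamma
moments, Newton inversion of the trigamma function) rather than numerical
maximum likelihood — robust at small gene counts and identical to
`limma::squeezeVar` (asserted to $10^{-6}$ in the tests). Moderated
t-statistics use $d_0 + df_g$ degrees of freedom; $d_0 \to 0$ reproduces
ordinary t, $d_0 \to \infty$ shrinks fully to $s_0^2$.

A gene is a DEG for a contrast iff (i) it is expressed (raw count > 0) in at
least 5% of the analysed MAIT cells (pooled across samples), (ii)
$|\hat\beta| \ge 0.4$, and (iii) BH-adjusted $p < 0.01$. The 0.05 FDR
convention used by some displays is available as a parameter. Genes failing
the 5% filter are excluded *before* weight computation: it matches the DEG
universe and stabilises the ZINB fits. `direction_summary()` tabulates
up/down calls per day and tests direction-by-time independence with an
uncorrected Pearson chi-square.

Why a mixed model at all: in a balanced design the subject effect cancels
exactly in time contrasts, making naive fixed-effects analysis conservative
rather than liberal — but droplet data is never balanced (cell yields per
sample vary severalfold). Under unbalanced sampling a real subject effect
makes the naive model understate uncertainty; the regression test in
`test-dewlmm.R` shows the naive model's null rejection rate inflating while
the mixed model holds its level. This is the model's raison d'être.

# Enrichment and activation

`enrich_test()` scores user-supplied GMT gene sets by the one-sided Fisher
exact test within a configurable universe (default: all genes passing the
5% expression filter — restricting the background to tested genes is the
defensible statistical choice when no curated knowledge base defines one).
Direction annotations (`GENE|+1` / `GENE|-1` suffixes in the GMT) enable the
activation z-score $z = (n_{\mathrm{consistent}} -
n_{\mathrm{inconsistent}})/\sqrt{n_{\mathrm{annotated}}}$ — the unweighted
sign-concordance form of the commercial pathway-analysis statistic, without
edge weights or bias correction. Calls: enriched at BH FDR < 0.05 (pathways)
or < 0.01 (regulators); activated/inhibited only when additionally
$z \ge 2$ / $z \le -2$. A set reported with $|z| < 2$ is "enriched-only"
even if a reader might informally describe its direction; the raw z is
always reported so either convention can be applied.

# Compositional microbiome analysis

Species tables are prevalence-filtered (nonzero in ≥ 60% of samples;
pathways 80% — fixed thresholds; no automated cutoff selection is
attempted). `dirichlet_clr_instances()` draws 128 Monte Carlo instances per
sample from Dirichlet(counts + 0.5) and applies the centred log-ratio
transform, following the ALDEx2 convention (Jeffreys-like prior, n = 128);
every CLR vector sums to zero to $10^{-8}$ by construction. Per feature:

* **Kruskal–Wallis** across the three conditions within each instance;
  reported p is the median over instances, BH-adjusted across features
  (significance at FDR < 0.10).
* **Welch t** between baseline and day 4 with a standardized effect,
  $(\mathrm{med}(day4) - \mathrm{med}(baseline)) / \max_g
  |x_{\mathrm{rand},g} - \mathrm{med}_g|$, the ALDEx2-style denominator with
  one random draw per group per instance; the reported effect is the median
  over instances, positive when day 4 is more abundant, with $|$effect$| >
  1$ the reporting cut. Random draws are keyed to the condition label so
  that swapping the pair flips every sign exactly (asserted).
* **Pathway ANOVA**: one-way ANOVA on CLR values (relative abundance
  optional), BH at FDR < 0.05.
* **Clustering**: Euclidean distance on the single CLR point estimate,
  average linkage, leaf orders and portable JSON trees for heatmap
  rendering (rendering itself is out of scope).

At these sample sizes (7 + 5 + 7) the KW-median-p route is conservative —
on the default simulation it often calls no species significant even when
every planted 16-fold shift is recovered at $|$effect$| > 1$. This mirrors
the known behaviour of the underlying method: its effect sizes, not its
rank-test p-values, carry most of the signal in small designs.

# The synthetic-data generator

`simulate_sc_counts()` draws ZINB UMI counts on the study layout: 7 subjects
× 4 time points × 50 cells (the study gated ~48 MAIT cells per sample).
Defaults, chosen once as a realistic droplet regime: baseline per-gene mean
counts lognormal(log 5, sd 1) at a $10^4$ library; library sizes
lognormal($\log 10^4$, 0.3); NB size 2; structural-zero probability
$\pi = \mathrm{logit}^{-1}(-1.5) \approx 0.18$, constant per gene
(matching the observational model of the dropout-weight method at
intercept-only complexity); subject SD $\tau = 0.3$; 10% DE genes at
$|\beta| = 0.6$ with mixed signs (`sign_mix = 0.5`), since the study
observed both up- and down-regulation. The two marker genes (KLRB1,
SLC4A10) are forced to ≥ 5 counts in designated MAIT-like cells and to
structural zero elsewhere, so gating can be validated against exact truth
labels with margin. `simulate_microbiome_counts()` draws multinomial counts
from softmax log-abundances with per-sample lognormal noise (sd 0.5),
structural sparsity (10%), depth $10^5$, on the 7 + 5 + 7 stool schedule
(two subjects missed the day-4 collection); planted species carry ±4 log2
day-4 shifts that revert by day 7, the rebound the intervention literature
reports.

What the generator does *not* emulate: ambient RNA, doublets, batch
effects, gene–gene correlation, taxonomic mis-assignment, or
compositional coupling between the planted DE genes and library size beyond
what closure induces. Passing tests therefore demonstrate correctness and
calibration of the statistics under the stated model, not robustness to
every artefact of real data.

One consequence of the log1p-CPM response deserves emphasis: a
multiplicative shift on the NB mean is attenuated on the log1p scale for
weakly expressed genes (and all-gene shifts cancel entirely under CPM
normalization). Coefficient recovery is therefore a property of the
estimator given its own model; the recovery experiments draw responses from
the mixed model directly, while count-level experiments assess *detection*
(sensitivity at the DEG criteria), where the tests require ≥ 0.6 at
$|\beta| = 0.8$ and observe ~0.9.

# Numerical choices and degenerate inputs

* QC boundaries are inclusive: exactly 200 or 7500 features, or exactly 10%
  mitochondrial reads, pass (only strictly worse cells fail — the literal
  reading of "> 10%", "< 200 or > 7500"). Mitochondrial genes are matched
  by the case-insensitive `MT-` name prefix (configurable), the 10x human
  reference convention.
* All-zero cells have `mito_fraction = 0` by convention and are removed by
  the feature filter; zero-total cells reaching `log_normalize()` are an
  error.
* Variable-gene ranking is the clipped-standardized-variance (vst) method:
  loess trend of log10 variance on log10 mean, z-scores clipped at
  $\sqrt{n}$; constant genes rank last. MAIT gating requires *both* markers
  strictly positive (cell-level conjunction; the cluster-level alternative
  is not implemented and the threshold is exposed).
* `fit_zinb_gene` starts from moment estimates and bounds
  $\mathrm{logit}\,\pi \in [-12, 12]$, $\log k \in [-7, 7]$; with no zeros
  the fit drives $\pi$ to the boundary ($< 10^{-5}$).
* Degenerate test inputs (identical values in every sample/group) return
  statistic 0 and p = 1 rather than 0/0.
* BH ties use the standard cumulative-minimum formulation (`p.adjust`).
* Duplicate GMT members are deduplicated (first annotation wins); a
  re-listed set name replaces the earlier definition with a warning.

# Problem sizes

The test suite and acceptance script run simulations sized for a laptop
core: null-FDR control uses 20 replicates (tests) / 5 replicates (script)
of 500 genes on the full 1400-cell design; parameter recovery uses 100
genes; ZINB recovery n = 5000; microbiome checks use the default 150-species
table with 128 CLR instances (16–64 in unit tests). The full suite completes
in about three minutes.

# Known limitations

* Dropout weights are intercept-only: no gene- or cell-level covariates in
  the zero-inflation model (the full factor-model generalisation is out of
  scope).
* The activation z-score omits the edge weights and bias correction of the
  commercial implementation; calls on sparse annotation overlaps are noisy.
* The per-gene model assumes a common $\beta$ across subjects; genuine
  subject-by-time interaction inflates $\sigma_g^2$ rather than being
  detected.
* Day-4 stool n = 5 limits the rank-based tests, as discussed above.
* The "expressed in ≥ 5% of MAITs" rule is applied pooled across samples;
  a per-condition rule would change the DEG universe at the margin.
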