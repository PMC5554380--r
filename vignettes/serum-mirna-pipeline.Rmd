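---
title: "Serum miRNA Ct-matrix analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum miRNA Ct-matrix analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirct)
```

# The analysis problem

`mirct` implements a complete analysis chain for circulating serum miRNA
studies based on TaqMan low-density-array (TLDA) qPCR cards, of the kind used
to search for non-invasive biomarkers that discriminate autism spectrum
disorder (ASD) from Tourette syndrome (TS), their comorbid presentation
(TS+ASD), and unaffected controls (NC). The raw material is a matrix of
cycle-threshold (Ct) values — miRNAs in rows, serum samples in columns — in
which a substantial fraction of wells is *flagged*: the amplification failed
or never crossed the detection threshold, so the recorded number is
meaningless. Everything downstream has to respect that mask.

The chain is:

1. **Reference profile and endogenous-control selection.** Serum has no
   agreed-upon reference miRNA, so controls are selected from the data. For
   the samples of one comparison, the per-sample median and mean Ct over the
   *complete* rows (a miRNA is dropped from these statistics if even one of
   its wells is flagged) form a reference profile that tracks the loaded
   cDNA mass on each card. Candidate controls are ranked by the Pearson
   correlation of their Ct vector with this profile; the most stable and
   abundant candidates become the endogenous controls.
2. **ΔCt normalization and fold changes.** ΔCt(miRNA, sample) =
   Ct(miRNA, sample) − mean Ct of the selected controls in that sample.
   Lower ΔCt means higher expression. Two-group contrasts use
   ΔΔCt = mean ΔCt(g1) − mean ΔCt(g2) and FC = 2^−ΔΔCt.
3. **Differential expression.** The profiling arm (a few samples per group,
   hundreds of miRNAs) is tested with a SAM-style two-class unpaired
   permutation test at an FDR cutoff of 0.15 with at least 100 permutations;
   the validation arm (tens of samples per group, one assay per miRNA) with
   ordinary one-way ANOVA plus Tukey's multiple comparisons at adjusted
   p ≤ 0.05, preceded by per-group normality checks (D'Agostino–Pearson K2
   and Shapiro–Wilk).
4. **Outlier screening.** Before group testing, candidate-group samples are
   screened once against mean ± 2·SD intervals on the marker ΔCt and the
   four ADOS item scores.
5. **Clinical correlation.** The marker ΔCt is correlated with IQ, YGTSS and
   the four ADOS items in general and class-specific scopes (a fixed family
   of 16 tests), using Pearson when both variables pass the normality check
   in scope and Spearman otherwise, with Bonferroni (α = 0.05/16 = 0.003),
   Holm (≤ 0.05), and Benjamini–Hochberg (≤ 0.01) corrections; correlations
   passing all three gates are followed up with ordinary least squares.
6. **Biomarker evaluation.** A univariate ROC curve over all ΔCt thresholds
   with the maximum-Youden cutoff (J = sensitivity + specificity − 1);
   a univariate logistic model; 100-repeat random sub-sampling
   cross-validation (2/3 train, 1/3 test); and a permutation test on AUC
   (100 label permutations, each re-evaluated by a 3-repeat CV, add-one
   p-value).
7. **Network and enrichment context.** Degree centrality on a seed +
   first-neighbor interaction subgraph, and hypergeometric
   over-representation with GeneRatio/BgRatio bookkeeping and BH ≤ 0.05.

# The statistical models

## SAM two-class statistic

For miRNA *i* with group means $\bar x_{i1}, \bar x_{i2}$ and pooled
standard error $s_i$,

$$d_i = \frac{\bar x_{i1} - \bar x_{i2}}{s_i + s_0},$$

where the fudge factor $s_0$ stabilizes the variance of $d$ for low-variance
rows. $s_0$ is chosen on the 5%-step percentile grid of the $s_i$ as the
value minimizing the coefficient of variation of the median absolute
deviation of $d$ across windows of $s$ — the original SAM recipe. The method
names the test but prints no formulas for its software's internals, so this
choice is documented here and `s0` can be overridden. FDR is calibrated by
permuting group labels (all $\binom{n}{n_1}$ assignments when that count is
within the permutation budget, random assignments otherwise). The q-value of
miRNA *i* uses the symmetric cutoff at $|d_i|$:

$$q_i = \hat\pi_0 \cdot
  \frac{\mathbb{E}_\text{perm}\,\#\{j : |d^*_j| \ge |d_i|\}}
       {\#\{j : |d_j| \ge |d_i|\}},$$

with $\hat\pi_0$ estimated from the fraction of observed $d$ falling inside
the interquartile band of the permuted statistics, clipped to 1, and
monotonized so q never decreases as $|d|$ decreases. Tests verify that this
matches an independent full-enumeration oracle exactly for small cohorts.

## Normality gate

The D'Agostino–Pearson omnibus statistic K2 combines the skewness transform
(D'Agostino 1970) and kurtosis transform (Anscombe & Glynn 1983) as
$K^2 = Z_1^2 + Z_2^2 \sim \chi^2_2$. No installed R package provides this
omnibus test, so it is implemented here and verified against frozen values
from an independent implementation. K2 needs n ≥ 8; below that the verdict
falls back to Shapiro–Wilk alone. The combined verdict is *non-normal* if
either test rejects in any involved group — a conservative rule that
switches the correlation analysis to Spearman whenever any distributional
doubt exists, and forces non-normal for constant vectors (where W is
undefined).

## ROC, cross-validation and the permutation null

AUC is computed by the trapezoid rule over the full threshold sweep and is
asserted (at 1e−12) to equal the Mann–Whitney pair statistic. Youden-optimal
cutoffs tie-break toward higher specificity, then lower threshold, making
output deterministic. CV splits are stratified by class — with a 1/3 test
fold in cohorts of ~55 this is the only way every fold reliably contains
both classes — and the averaged ROC is the vertical average of TPR on a
101-point FPR grid, since "average ROC" is otherwise underdetermined.
Reported CV sensitivity/specificity are computed from each sample's
predicted probability averaged over the repeats in which it was in the test
fold, classified at 0.5. The permutation p-value uses the add-one rule
$(b+1)/(m+1)$, which cannot return 0. The observed statistic is evaluated by
the same short inner CV as each permuted replicate, so the comparison is
like-for-like.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| flagged-well sentinels | `Undetermined`, `NA`, empty | — | instrument exports differ; configurable |
| controls selected (k) | 3 | miRNAs | "top three stable" normalization |
| stability pool (m) | 10 | miRNAs | the abundance preference needs a pool; see below |
| SAM FDR cutoff | 0.15 | — | the discovery-arm operating point |
| SAM permutations | ≥ 100 | — | exhaustive when fewer assignments exist |
| outlier half-width | 2 | SD units | the mean ± 2·SD rule |
| correlation family (m) | 16 | tests | the planned-family divisor; NT records keep their slot |
| regression gates | 0.003 / 0.05 / 0.01 | p | Bonferroni / Holm / BH thresholds, all required |
| CV repeats | 100 | — | repeated random sub-sampling |
| train fraction | 2/3 | — | 2/3 train, 1/3 test |
| permutations (AUC test) | 100 | — | with 3-repeat inner CV each |
| enrichment significance | 0.05 | BH p | conventional ORA threshold |

# The synthetic-data generator

`sim_config()` fixes the study conditions; the generators are first-class,
tested code, not ad-hoc fixtures.

**Profiling arm.** Two 377-miRNA panels over 4 ASD / 5 TS / 4 TS+ASD / 3 NC
sera. Each well is baseline(miRNA) + loading(sample) + marker effect +
noise. Baseline Ct means are uniform on [22, 35] and per-miRNA SDs uniform
on [0.5, 1.5] cycles — serum TLDA papers do not publish distributional
parameters for raw Ct, so these are stated, deliberately broad choices, not
estimates. The per-sample loading offset (SD 0.5 cycles) is the quantity the
reference profile is designed to recover. Three designated control rows
carry near-zero residual SD and sit in the abundant 22–26 Ct range. Wells
are flagged independently at 5% by default (missing at random); an optional
mode biases flagging toward high-Ct rows because real undetermined wells are
abundance-dependent.

Note that at the profiling arm's own group sizes a two-class test of 4 vs 3
sera admits only 35 distinct label assignments, which bounds the resolution
of any permutation-calibrated q-value; with per-miRNA noise up to 1.5
cycles, discovery-scale detection of even a 3-cycle shift is intrinsically
marginal. This is why such designs treat profiling as a screen and confirm
candidates in a larger validation cohort — the structure this package
mirrors. (The suite's SAM power checks therefore use an 8+8 design, where
the test's operating characteristics can be asserted sharply.)

**Validation arm.** A 30/24/25/25 ASD/TS/TS+ASD/NC cohort. The marker ΔCt
in group *g* is Normal(μ_g, 0.9) with μ = 2.0 (ASD), 2.75 (TS), 3.0
(TS+ASD), 2.7 (NC): the positive class sits at lower ΔCt (upregulated in
ASD), and the separations are chosen so that single-marker discrimination
lands in the AUC ≈ 0.7–0.8 range that motivates this kind of analysis —
detectable but far from clean separation. YGTSS is generated as
4.537·ΔCt − 3.269 + Normal(0, 5) and then rounded and clamped to 0–100;
rounding is applied last, so the latent linear model is exact and is exposed
in the ground-truth record for exact-recovery tests. ADOS items and IQ are
group-conditional Gaussians (NC items fixed at 0), rounded to integers.

**What the generator does not emulate:** panel-specific miRNA identities or
sequence content, hemolysis and other pre-analytic artifacts, correlated
miRNA co-regulation, batch structure across cards, age/sex effects on the
clinical scales, and the clamping-induced floor effects of real score
distributions beyond simple truncation. Passing tests therefore demonstrate
that the *procedures* are implemented correctly and calibrated under their
stated assumptions — not that any particular serum marker generalizes.

# Design choices where the method description is open

* **Which profile to correlate against.** Both the median and the mean
  profile are computed; the ranking defaults to the average of the two
  correlations and reports each separately (`rank_by` switches to a single
  profile). The procedure computes both but does not say which one drives
  the ranking.
* **Stability vs abundance.** Controls should be both stable and abundant.
  Implemented as a two-stage rule: take the top *m* = 10 by correlation,
  keep the *k* = 3 with the lowest mean Ct. This reproduces the stated
  preference without inventing a joint score; `m = k` disables the abundance
  stage.
* **Tie-breaking** in the ranking is by lower mean Ct, then lexicographic
  id; zero-variance rows have undefined correlation and are dropped with a
  message (a constant row carries no profile information).
* **Per-comparison recomputation.** The reference profile, exclusion set and
  ranking are rebuilt for each two-group comparison rather than once
  globally, mirroring the per-comparison matrices of the original workflow.
* **ΔCt reference combination.** The per-sample reference is the arithmetic
  mean of the selected controls' Ct; the source procedure does not state the
  combination rule.
* **Outlier rule.** "Value and/or score" is ambiguous; both combinations are
  implemented. The default is AND (expression outlier *and* at least one
  item outlier), which matches the reported exclusions being outliers on
  both axes; `rule = "or"` gives the liberal reading. SD uses the n−1
  sample convention, also unstated in the source.
* **Correlation family size** is fixed at 16 planned tests regardless of NT
  cells, matching the printed α = 0.05/16 divisor. Spearman CIs use the
  Fisher-transform approximation (the original CI method is unstated). The
  "BH (FDR 1%)" label conflates an adjusted p with a level; this package
  reports BH-adjusted p and applies the ≤ 0.01 decision rule.
* **Logistic separation fallback** is a lightly ridge-penalized fit
  (λ = 0.01 on the slope), flagged in the result, since perfectly separated
  small cohorts otherwise have divergent ML estimates.
* **Enrichment background** defaults to the annotated universe of the
  gene-set file ("entire genome" operationalized as the annotated universe,
  which is what published GeneRatio/BgRatio pairs imply); it is overridable.
  Terms with zero query hits are not emitted, and the BH family is the set
  of emitted terms.

# Numerical and degenerate-input behavior

Ties in ΔCt thresholds contribute 1/2 to the rank AUC and are handled by the
trapezoid sweep identically. Flagged wells can never reach arithmetic:
accessors mask them to `NA`, and tests poison flagged cells with absurd
values to prove downstream invariance. A flagged control well invalidates
that sample's reference — an error by default, or the sample is dropped when
requested. Exhaustive permutation enumeration replaces sampling whenever the
assignment count is within budget, which both removes Monte-Carlo noise and
lets tests compare against full-enumeration oracles. All stochastic
operations take explicit integer seeds and are bit-reproducible.

# Problem sizes used by the test suite

The suite's calibration experiments use 200 seeds for the permutation
type-I-error and ANOVA-uniformity checks, 100 Gaussian replicates for the
2σ screen rate, 200 simulated cohorts (n = 104, σ = 5) for slope recovery,
20 seeds × 100 CV repeats for the binormal AUC check, and 50 seeds of a
201-miRNA, 8+8 profiling design for SAM detection. These sizes give
Monte-Carlo standard errors comfortably inside the asserted tolerances while
keeping a full run of the suite in the minutes range on one CPU.

# Known limitations

Single-marker evaluation only (no multivariate panels); no DeLong CI for
AUC (a bootstrap CI is provided); no covariate adjustment in the correlation
analysis; no robust (median/MAD) outlier variant; no global-mean or quantile
normalization alternatives; the network module consumes a prepared edge list
and computes degree only. These mirror the scope of the analysis the package
implements rather than technical constraints.
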