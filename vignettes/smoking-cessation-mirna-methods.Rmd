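---
title: "Methods: smoking-dependent miRNAs and their reversibility after cessation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoking-dependent miRNAs and their reversibility after cessation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saemir)
```

# The scientific question

Cigarette smoke dysregulates gene expression in the small airway
epithelium (SAE), the cell layer lining bronchi of generation six and
beyond where chronic obstructive pulmonary disease and most lung cancers
begin. Part of that dysregulation is mediated by microRNAs. The question
this package addresses is two-fold: which miRNAs differ between smokers
and nonsmokers, and — because disease risk persists after quitting — which
of those changes fail to reverse after months of smoking cessation.

The cohort design is three groups with a paired arm: healthy nonsmokers,
healthy smokers at baseline, and the same smokers re-sampled after
cessation ("quitters"). The analysis chain is:

1. per-miRNA two-factor ANOVA (group + gender) with Fisher LSD contrasts;
2. selection of *smoking-dependent* miRNAs (smoker vs nonsmoker,
   p < 0.01 and |fold-change| > 1.5, strict);
3. classification of each signature miRNA as *cessation-persistent*
   (quitter vs nonsmoker, p < 0.05 and |fold-change| > 1.5) or
   *reversible*, plus a per-miRNA percent-change reversibility statistic;
4. a per-subject *smoking-dependent miRNA index* counting quartile
   exceedances, compared across groups by Kruskal-Wallis and Dunn tests;
5. hypergeometric enrichment of miRNA functional categories and of the
   expression-filtered target genes of the persistent miRNAs.

# The model and its assumptions

## Two-factor ANOVA with Fisher LSD contrasts

For each miRNA, log2 expression is modelled additively as
$y = \mu + \alpha_{group} + \beta_{gender} + \varepsilon$, with no
interaction term and Gaussian residuals. Gender enters because it is a
known source of variation in these cohorts; the quitter samples are
treated as an independent third group (the pairing with baseline smokers
is ignored), keeping one coherent group-based model for every contrast.
Sums of squares are Type II, which for an additive model is invariant to
factor order in an unbalanced design.

Each pairwise comparison is a Fisher least-significant-difference
contrast: $t = (\bar y_a - \bar y_b)/\sqrt{MSE\,(1/n_a + 1/n_b)}$ on the
residual degrees of freedom of the full ANOVA, without family-wise
adjustment. In a two-group design with no covariate this reduces exactly
to the pooled-variance two-sample t-test (verified in the test suite).
The quitter-vs-nonsmoker persistence p comes from the same three-group
fit. Benjamini–Hochberg q-values are reported as an informational column;
the selection gates use raw p, matching the published criteria.

Fold-changes are anti-logged differences of group mean log2 values and
use the signed convention with magnitude ≥ 1: `signed_fold_change(d)`
returns $2^d$ when $2^d \ge 1$ and $-2^{-d}$ otherwise, so a halving is
written −2.0. Whether the original analysis anti-logged mean log values
or averaged linear values is not derivable from the tables; the log-mean
convention matches the log-scale ANOVA and is used throughout.

## Reversibility

Percent change is computed on linear-scale (anti-logged per-sample, then
averaged) group means:
$$\%\,change = 100\,\frac{\bar x_{smoker} - \bar x_{quitter}}
                          {\bar x_{smoker} - \bar x_{nonsmoker}}$$
100 means full return to the nonsmoker level, 0 no change; values outside
[0, 100] (overshoot, further departure) are legitimate and retained. The
statistic is invariant to negating all three means, so up- and
down-regulated miRNAs are treated symmetrically. When the
smoker–nonsmoker denominator is smaller than a 1e-9 relative tolerance
the record is flagged undefined rather than aborting the pipeline.

## The smoking-dependent miRNA index

For each signature miRNA the first and third quartiles of nonsmoker
expression are computed with the interpolation rule that places the k-th
of n sorted values at probability $(k-1)/(n-1)$ (R's default type-7
quantile; the exact rule used upstream of the printed results is unknown,
so a single deterministic convention is fixed and documented). A subject's
index is the count of signature miRNAs whose value is strictly above the
third quartile (up-regulated miRNAs) or strictly below the first quartile
(down-regulated miRNAs); boundary ties score 0. The index is invariant
under any strictly monotone transform applied jointly to the values and
thresholds, so it measures rank position only. One fixed
nonsmoker-derived threshold set is used for all three groups. Group
differences are tested by tie-corrected Kruskal-Wallis with Dunn's
pairwise z tests on the pooled ranks (unadjusted p, with a Bonferroni
column; the appropriate adjustment convention is left to the reader since
none is canonical here). When every index value is tied there is no rank
information and H is reported as 0 with p = 1.

A useful calibration fact: if the thresholds were the *true* quartiles of
the nonsmoker distribution, a held-out nonsmoker would score each miRNA
with probability exactly 1/4, so the expected index is a quarter of the
signature size. With *empirical* type-7 quartiles from only n = 9
nonsmokers the third quartile is exactly the 7th order statistic, and a
fresh draw exceeds it with probability $(n-k+1)/(n+1) = 0.3$, not 0.25 —
a finite-sample inflation worth remembering when comparing index values
across cohorts of different size. Both facts are verified in the test
suite (the 1/4 law against distributional quartiles, the 0.3 rate as an
order-statistic property at n = 9).

## Enrichment

Category and pathway enrichment both use the hypergeometric upper tail
$P[X \ge k]$ for a query of size m with k hits in a size-K set drawn from
a size-N universe — identical to the one-sided Fisher exact test for
over-representation, which is why a single implementation serves both.
Fold-enrichment is $(k/m)/(K/N)$ and satisfies
$fold \cdot (K/N) \cdot m = k$ exactly (asserted in tests). Annotation
databases are consumed as plain files (GMT sets, a two-column target map,
an RPKM table), never queried as services, so the statistics are
reproducible. Predicted target genes are filtered to those expressed in
the SAE, RPKM strictly greater than 0.125; the pathway universe defaults
to the expressed gene list.

## Comparative CT

qPCR validation data are reduced by the comparative-CT method: per sample
ΔCt = target Ct − endogenous-control Ct, ΔΔCt subtracts the reference
group's mean ΔCt, and the relative quantity is $2^{-\Delta\Delta Ct}$, so
one cycle of advantage doubles the estimate.

# The synthetic cohort generator

`cohort_design()` defaults encode the study conditions: 9 nonsmokers,
10 smokers re-sampled as quitters, 1100 miRNAs, 25 planted up- and 9
down-regulated features, and a persistence fraction of 12/34. Log2
expression is baseline (7.0) + group shift (±`effect_log2`) + gender
effect (+0.3 for males, a modest covariate effect chosen so the two-factor
model has something to adjust for; the study reports no magnitude) +
Gaussian noise. Persistent features keep their shift in quitters;
reversible ones return to baseline. Quitter noise is drawn fresh, so with
the default `subject_sd_log2 = 0` the paired structure carries no
artificial correlation — matching the group-based analysis model; a
subject random intercept is available for sensitivity work. Genders
alternate within groups to near-balance (4/5 and 5/5 at the study sizes).
`effect_log2 = 1.5` and `noise_sd_log2 = 0.5` are calibration choices
(the study reports no effect or variance estimates); recovery checks use
`effect_log2 = 2.0`, where the planted signature is essentially always
recoverable at these sample sizes.

`generate_annotation_resources()` builds matching annotation inputs: one
miRNA category enriched for the planted features at a configurable fold
among random decoys, a random target map over a synthetic 2000-gene
universe with one pathway constructed to overlap the persistent-miRNA
targets, and RPKM values straddling the 0.125 expressed-gene cut.

What the generator deliberately does **not** emulate: probe-level and
batch effects, array spatial artifacts, heavy-tailed or
intensity-dependent noise, correlated miRNA families, and realistic
annotation topology. Passing tests therefore demonstrate that the
*procedures* are correct and calibrated under their own assumptions, not
that the biological conclusions transfer to any particular real cohort.

# Numerical choices and degenerate inputs

- Strict inequalities everywhere the criteria are stated strictly
  (selection, persistence, RPKM filter, index thresholds). Tables
  transcribed from print carry fold-changes rounded to one decimal; the
  `printed_decimals` argument of the gates widens the fold-change
  threshold by half an ulp of that precision so a printed 1.5 — an
  underlying value that exceeded 1.5 before rounding — is retained.
- Zero residual variance in a per-miRNA fit, groups with fewer than two
  samples, fewer than four nonsmokers for quartiles, empty queries and
  empty reference groups are all hard errors; an undefined percent-change
  denominator is a flagged record, not an error.
- Missing or non-finite expression values are format errors at read time,
  never imputed — silent imputation would corrupt the quartiles.
- Hierarchical clustering uses 1 − Pearson correlation with average
  linkage; merges are processed in input order, so results are
  deterministic for a given matrix.
- Problem sizes in the test suite (50-seed recovery and null-calibration
  runs at the full 1100-miRNA scale, 2000-permutation and 500-draw
  oracles) were chosen as the smallest sizes at which the Monte-Carlo
  error bounds quoted in the tests are meaningful.

# Known limitations

- The quitter group is modelled as independent; a paired (subject-level)
  analysis would be more powerful for the cessation contrast but would
  not reproduce the published group-based procedure.
- No moderated variance estimation: with n ≈ 10 per group, per-feature
  MSE is noisy, and empirical-Bayes shrinkage (as in limma) would change
  the gate's operating characteristics. Raw-p gating without multiplicity
  control is kept for fidelity; q-values are reported alongside.
- Array normalization is out of scope; input matrices are assumed
  pre-normalized and log2-scaled.
- The index's finite-sample quartile bias (0.3 vs 0.25 exceedance at
  n = 9) means index magnitudes are only comparable between cohorts with
  the same number of nonsmokers.
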