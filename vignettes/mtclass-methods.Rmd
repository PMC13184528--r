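---
title: "Classification-based ranking of multivariate cis-eQTLs: models and methods"
author: "mtclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification-based ranking of multivariate cis-eQTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtclass)
```

## The problem and the model

Classical cis-eQTL mapping regresses one expression phenotype on genotype,
one tissue (or exon, isoform, cell type) at a time. When a variant's
regulatory effect is spread across many correlated phenotypes — or when it
changes the *shape* of the expression distribution rather than its mean —
single-phenotype linear tests and their multivariate generalizations (MANOVA,
reverse regression) lose power, because they are mean-shift tests by
construction.

`mtclass` inverts the question: instead of asking whether genotype predicts
expression, it asks how well donor genotype can be *recovered* from the
donor's expression vector by a supervised classifier. Genotypes are collapsed
to a dominant binary coding (carrier of at least one alternate allele vs
reference homozygote), a classifier is trained to separate the two classes
from the multi-phenotype expression vector, and the cross-validated
classification quality — macro F1 and the Matthews correlation coefficient
(MCC) — becomes the association score used to rank (gene, variant) pairs.
A variant whose genotype is recoverable from expression is, by definition,
associated with it, whatever the functional form of the association.

The classifier is a soft-voting ensemble of a probability random forest (100
trees) and an RBF-kernel support vector machine with Platt-type probability
calibration (C = 1): class probabilities are averaged and the argmax is the
prediction, with exact ties resolved to the non-carrier class so that output
is deterministic. For two-dimensional exon-by-tissue grids the ensemble is
replaced by a single-hidden-layer perceptron whose hidden size is
`ceiling(m * n / 2)` for an `m` exon by `n` tissue grid — large enough to
capture cross-axis structure, small enough to fit on cohort-scale samples.

## Cross-validation, scoring, and aggregation

Scores come from stratified four-fold cross-validation. Variants with fewer
than four donors in the minority class are excluded, so every fold holds at
least one minority donor. Within each fold the features are z-scored — with
mean and *population* standard deviation estimated on the training rows only
and applied to the held-out rows. This leakage-free standardization is the
default; a `global_zscore` switch standardizes once on all donors for users
who want the simpler convention. Out-of-fold predictions are pooled into a
single confusion matrix per run and macro F1 / MCC are computed on it;
pooling (rather than averaging per-fold metrics) keeps both metrics
well-defined even when one fold happens to contain a single class among its
test donors.

Because fold assignment and learner initialization are stochastic, the whole
procedure is repeated (three times by default) with consecutive seeds, and
the per-pair score is the *median* across iterations. In the pipeline every
(gene, variant) pair gets its own seed derived from the global seed plus a
hash of the variant ID, which makes results byte-identical regardless of how
pairs are distributed over worker processes.

MCC is reported on its natural [-1, 1] scale; degenerate confusion matrices
(any zero marginal) map to 0 rather than NaN. Macro F1 treats any 0/0
precision-or-recall term as 0.

## Selection and preprocessing rules

* **Gene filter**: genes with zero expression in more than half of all
  samples are removed; the top 50% of the survivors by cross-sample variance
  are kept (ceiling on odd counts, variance ties broken by gene ID).
* **cis-window**: candidate variants lie within 10 kb of the gene body,
  inclusive at both boundaries. The gene-body span is used because "coding
  region" is not a reproducible coordinate set; the window is configurable.
* **MAF**: at least 0.05, computed from non-missing dosages, boundary
  inclusive.
* **Call rate**: variants below 90% genotyping rate are removed first, then
  donors below 90% over the remaining variants; analysis is restricted to
  autosomes. Variant-before-donor ordering is a fixed convention (the two
  filters do not commute).
* **Dominant binarization**: dosage 0 maps to 0; dosages 1 and 2 map to 1.
  This pools heterozygotes with alternate homozygotes to keep the minority
  class large enough to learn from at cohort-scale sample sizes.

### Missing expression: predictive mean matching

Donor-by-feature expression blocks assembled across tissues are often
heavily incomplete. Missing cells are imputed by predictive mean matching
with chained equations: each feature with missing cells is regressed by OLS
on all other features over its observed rows, and every missing cell is
filled with the *observed* value of one of the `k = 5` donors whose
predicted mean is closest (drawn uniformly). Cells are initialized at the
feature mean, 10 sweeps are run per imputation, and 5 independent
imputations (seeds `seed + 0..4`, same visit order) are averaged. Because
PMM only donates observed values, single imputations stay in the observed
support, and the average stays within each feature's observed range;
observed cells are returned bit-identical. The neighbor count, sweep count,
and imputation count are standard defaults for this family of imputers and
are all configurable.

### Single-cell input

Raw UMI counts are log-normalized (`log(1 + count * 1e4 / cell_total)`;
the scale factor 10,000 is the common single-cell convention), the 3000
most variable genes are retained (ties at the boundary broken by gene ID),
and per-donor, per-cell-type *pseudobulk* values are formed by summing the
normalized expression of all cells of that type. Only cell types observed
in every donor are kept as features, so the resulting matrix has no missing
cells by construction.

## Linear baselines

Three comparators operate on the same binarized genotypes:

* **MANOVA**: for two groups, one-way MANOVA is exactly Hotelling's
  T-squared, so it is implemented directly as
  `T2 = (n0 n1 / n) d' S^-1 d` with the pooled covariance `S`, converted to
  an exact F statistic. Zero-variance and collinear features are dropped
  before inversion (this is where linear methods fail on all-zero features
  while the classifier does not). The implementation is cross-checked in the
  tests against the Hotelling–Lawley statistic of `stats::manova()` and, at
  p = 1, against the pooled-variance t-test.
* **Reverse logistic regression**: genotype regressed on all features
  jointly, likelihood-ratio chi-squared against the intercept-only model.
  Under separation or non-convergence a lightly ridge-penalized IRLS
  (lambda = 1e-6) provides the fit, flagged in the output. With binarized
  genotypes an ordinal reverse regression collapses to this binary logistic
  form.
* **Cauchy combination**: per-feature Welch t-tests combined as
  `p = 0.5 - atan(mean(tan((0.5 - p_i) pi))) / pi`, valid under dependence.
  Inputs are clipped to `[1e-15, 1 - 1e-15]` to keep the tangent finite;
  the k = 1 case is the identity. The Welch t-test is used as the
  single-feature test feeding the combination; it is robust to the unequal
  class variances that the variance-only scenario creates by design.

## Evaluation statistics

* **GWAS colocalization**: hits are unique catalog positions within 10 kb
  (inclusive) of a variant. When the top-N cut would bisect a block of tied
  scores, the prefix is extended to the smallest M ≥ N that respects the tie
  block, and the raw hit count is rescaled by N/M. The hit curve is emitted
  cumulatively over the prefix grid.
* **Disease-gene overlap**: disease genes are first filtered to the tested
  background, then the first 100 *unique* eGenes in rank order are
  intersected with them.
* **Chromatin states**: BED segments are loaded with `rtracklayer`, so the
  0-based half-open BED convention maps to 1-based closed ranges: a variant
  at 1-based position p lies in segment (s, e] iff s < p <= e. Enrichment of
  top variants against the remaining tested variants uses two-sided Fisher
  exact tests with Benjamini-Hochberg correction across states within a
  tissue. Positions outside every segment are labelled "Unannotated".
* **LD pruning**: genomic-order scan dropping any variant with squared
  Pearson correlation above 0.50 against a retained variant within a
  200-variant window. The comparison keeps pairs whose r-squared equals the
  threshold up to double rounding (the rule is strictly greater-than);
  r-squared against a zero-variance vector is defined as 0.
* **Differential eQTLs**: variants at or above the 90th percentile of median
  macro F1 whose p-values in *every* baseline are at or above that
  baseline's own 10th percentile, with percentiles computed on the shared
  (post-pruning) variant universe (`stats::quantile` type 7).
* **Region enrichment**: the MHC default is the canonical GRCh38 span
  chr6:28,477,797-33,448,354 (configurable). The 2x2 table contrasts the
  selected set against the *whole* universe, matching the
  selected-vs-genome-wide arithmetic under which the published odds ratios
  reproduce from their proportions; odds ratios with a zero cell get the
  Haldane-Anscombe 0.5 correction on all four cells.

## The simulation engine

The generator draws Hardy-Weinberg genotypes at a configurable MAF and
correlated expression from a multivariate normal with unit variances,
exchangeable correlation rho (an arbitrary correlation matrix can be
supplied), and baseline mean 1 — non-zero so that the multiplicative
geometry, which scales the mean by `(1 + effect)^dosage`, is not a no-op.
Effect geometries: carrier mean shift, additive and multiplicative dosage
effects, carrier-only variance inflation (means untouched), and an
interaction pattern that shifts carriers by `+/- effect` with alternating
sign across features, so pooled per-feature mean differences cancel while
the multivariate pattern remains separable. MCAR missingness (cell-wise or
per-feature rates) emulates the incomplete donor-by-tissue blocks of real
multi-tissue cohorts.

Default study conditions used throughout the tests and the acceptance
script: n = 200 donors, p = 9 features, rho = 0.3, MAF 0.3 (roughly balanced
classes after dominant collapse), effect grid {0.5, 1, 2, 5}, variance
ratios up to 3, 100 replicates for power contrasts and 2000 for null
calibration, with a 500-replicate permutation reference for the classifier's
null mean (the standard error of that mean is about 0.005, far inside the
band being checked). These sizes resolve the qualitative contrasts of
interest on a single CPU; they are the package's chosen desk-scale
conditions, not estimates of any cohort's parameters.

What the simulations do *not* emulate: LD structure between variants
(genotypes are drawn independently), count-distributed expression
(a negative-binomial layer would be needed), donor covariates, and
structured (non-MCAR) missingness. Passing the simulation-based checks
therefore demonstrates correctness of the algorithms under the stated
geometry, not performance on any particular cohort.

## Numerical and design choices

* Population (n-denominator) standard deviation in the z-score; a
  zero-variance feature maps to all zeros rather than NaN.
* Fold assignment retries: if a training fold ends up single-class, the
  split is redrawn with a shifted seed, at most five times, then the variant
  is skipped with a warning.
* The perceptron uses `nnet`: a single hidden layer (size `ceil(mn/2)`),
  logistic activations, BFGS optimization with an iteration cap of 500, and
  softmax outputs. The hidden-size rule is the modeling commitment; the
  activation/optimizer pairing is the standard choice for compact
  single-hidden-layer networks in R and behaved equivalently at these
  problem sizes.
* The SVM's probability calibration can fail on very small minority classes;
  the ensemble then falls back to the hard margin prediction as a degenerate
  probability for that learner (the forest still contributes calibrated
  probabilities).
* p-values are floored at 1e-300 so extreme statistics stay inside (0, 1].
* Multiallelic VCF records are skipped by default (with a warning) or split
  into per-allele records on request; how multi-allele indels should be
  dosage-coded is genuinely ambiguous, so no silent default is imposed.
* Benchmark and calibration runs score each replicate with a single CV run;
  the three-iteration median is the pipeline default for ranking real data,
  where per-pair stability matters more than aggregate summaries.

## Known limitations

* The ensemble's absolute scores depend on classifier hyperparameters; the
  ranking is the stable output, and hyperparameters are recorded in the JSON
  sidecar of every run.
* Covariate adjustment (age, sex, ancestry PCs) is not implemented; inputs
  are assumed pre-residualized if that matters.
* Classification scores are not p-values; permutation would be needed to
  attach error rates to a score threshold.
* The LD pruner uses in-sample genotype correlations, not an external
  reference panel.
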