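---
title: "Pooled case-control proteomics inference: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled case-control proteomics inference: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolprot)
```

## The design this package models

A pooled case-control proteomics study contrasts a case plasma pool
(equal volumes from ~100 future cases) against a matched control pool,
labeled with heavy and light acrylamide respectively (or vice versa),
mixed, fractionated and analyzed by LC-MS/MS. Each pool pair yields
heavy/light peak-area ratios for cysteine-containing peptides; with
eight pool pairs per disease, protein-level inference about case-control
differences becomes possible despite the small number of replicates,
because information is shared across proteins and diseases.

`poolprot` starts where peptide heavy/light ratios exist. Everything
upstream — identification, protein grouping, peak-area extraction — is
out of scope; protein group ids are taken as given and aligned across
experiments by id.

## Quantification rollup and normalization

Each peptide's measured `log2(heavy/light)` is oriented to case/control
by the per-experiment sign `x_i` (+1 when the heavy label was on the
case pool). Per protein per pool pair, the cell value `y_gi` is the
**median** of the oriented peptide log2 ratios and its weight `w_gi` is
the count of contributing peptide ratio records. Three choices here
were genuinely open:

* *Median versus mean per cell.* The summary of peptide-level ratios is
  unspecified in this design's tradition; the median is robust to the
  occasional mis-assigned or interfered peptide ratio, and the mean is
  available via `rollup(..., summary = "mean")`. With symmetric noise
  both are unbiased.
* *Weights.* "Number of quantified peptides" counts ratio records, not
  unique sequences (`unique_peptides = TRUE` gives the alternative). The
  weights enter weighted least squares as relative precisions; they are
  deliberately not normalized, since weighted least squares is invariant
  to their overall scale (asserted by test).
* *Centering level and order.* Ratios are median-centered to zero
  **per experiment**, at the protein level, after rollup and before
  exclusions, so the centering constant `c_e` does not depend on which
  proteins survive filtering. Centering at the peptide level would give
  slightly different constants; the protein level is the default because
  downstream inference operates on protein cells.

Median centering has one consequence worth stating: a labeling bias
`lambda` shared by all proteins is constant within an experiment, so
centering removes most of it (the median protein is null). The label
covariate in the model then absorbs what remains; on synthetic data the
fitted `lambda_g` is therefore near zero even when the generator's bias
is large. This is the intended division of labor, not a failure to
recover the parameter.

Exclusion rules are applied per disease in a fixed order, with each
dropped group attributed to the first triggering rule: depletion-target
membership, all-defunct annotation, fewer than 4 peptide ratios across
the disease's experiments, and quantification in fewer than 2 pool
pairs. The counts reconcile with the input total in the run report.

## The per-protein model and variance moderation

For protein `g`, observed cells across **all** diseases are fit jointly:

`y_gi = mu_g,d(i) + lambda_g * x_i + e_gi`, weights `w_gi`.

Joint fitting buys residual degrees of freedom for variance estimation
when each disease alone has only eight pairs. `lambda_g` is a single
shared coefficient per protein (per-disease labeling coefficients via
`per_disease_lambda = TRUE`); when the observed rows make `x`
collinear with the disease means — notably a disease whose heavy label
was always on the case pool, analyzed alone — the covariate is dropped
and the protein flagged `aliased`, so the disease mean remains
estimable and the labeling effect is simply not identified from that
slice of data.

Variance moderation follows the standard empirical-Bayes construction:
residual variances are modeled as scaled chi-square draws around a
scaled-F prior, and `(d0, s0^2)` are estimated by matching the mean and
dispersion of `log s2_g` through digamma/trigamma identities, with a
Newton inverse of the trigamma function. When the observed dispersion
does not exceed what equal true variances would produce, `d0 = Inf`
(complete shrinkage) is returned. The moderated t uses
`s_tilde^2 = (d0 s0^2 + d_g s2_g)/(d0 + d_g)` on `d0 + d_g` degrees of
freedom (normal reference in the infinite limit). One hyperparameter
pair is estimated over all proteins of all diseases — the
degrees-of-freedom motivation for joint fitting applies equally to the
prior.

FDR control is Benjamini-Hochberg, separately per disease; the step-up
formula supports adjusting a truncated list (the smallest p-values)
against a stated total, which is how published top-ranked excerpts are
round-tripped.

Two approximations deserve honesty. The weights treat cell variance as
proportional to `1/w`, but protein-by-experiment noise adds a constant
component, and the median rollup changes the peptide-noise constant; in
null simulations at the default study conditions the realized type-I
rate at nominal 0.05 is about 0.053–0.061 — mildly anti-conservative,
inside the binomial 99% band used in the test suite, and inherent to
count weights rather than to this implementation.

## Protein-set testing

Sets with at least 3 quantified member proteins for a disease are
tested with a regularized Hotelling statistic. Member values are first
label-adjusted (`y_gi - lambda_g x_i`) so a labeling bias cannot
masquerade as a coordinated set shift; missing cells are imputed with
the protein's own mean over observed pairs (reported per set), because
complete-case deletion would interact with the minimum-size rule. With
row means `ybar` and covariance `S` across the `n` pairs,

`T2 = n * ybar' (S + rI)^{-1} ybar`, `r = ridge_frac * mean(diag(S))`.

The ridge choice is scale-equivariant and keeps `S + rI` invertible
when the set size approaches or exceeds `n` (nine glycolytic enzymes
against eight pool pairs is a realistic case). `ridge_frac = 0.5` by
default; `T2` is monotone non-increasing in the ridge, so the choice
trades power for stability rather than validity — validity comes from
the null, not the statistic.

The null is the exact sign-flip distribution: under no case-control
difference each pair's ratio vector is symmetric about zero, so all
`2^n` column sign assignments are equally likely. At `n = 8` all 256
are enumerated and the p-value counts the identity in numerator and
denominator. Because `T2` is even in the data, the global flip always
ties the identity, so the sharpest attainable p is `2/256` (the
enumeration bound `1/256` is a floor, not an attained value). Beyond
the budget, Monte-Carlo sampling with the add-one estimator is used.
An asymptotic reference was deliberately avoided: with eight pairs,
chi-square approximations to a ridge statistic are untrustworthy and
enumeration is cheap.

## Replication statistics

Matched-pair immunoassay data are summarized by the geometric mean of
within-pair ratios with a one-sample t interval on the log scale;
covariate adjustment regresses the log-ratios on pair-level covariates
and reports the exponentiated intercept. Quartile analyses cut the
pooled concentration distribution at its quartiles (ties to the lower
group) and fit **unconditional** logistic regression with matching
factors as covariates — conditional likelihood is out of scope, and the
covariate-adjustment reading of "control for matching factors" is the
implemented one. The trend test is the Wald test on the quartile entered
as ordinal score 1–4 (a median-per-quartile scoring would be an
alternative; the ordinal score is the default and labelled as such).
Separation in the logistic fit raises an error recommending exact or
penalized methods rather than reporting an untrustworthy Wald interval.
Fold-change projection uses `OR = exp(beta ln g)` with normal-quantile
(1.96) intervals, matching the large-sample Wald style of the other
ratio intervals.

## What the synthetic generator emulates — and what it does not

`pool_sim_config()` defaults encode the discovery design: two diseases,
8 pool pairs each, heavy label always on the case pool for CHD and
randomly assigned for stroke, ~400 quantifiable proteins (the
filtered analysis sets are in the mid-300s), 10% of proteins carrying
true effects of magnitude 0.4 log2 units (the scale of the largest
tabulated case/control ratios), a labeling bias of 0.15 log2 units,
protein-by-experiment noise SD 0.2, peptide noise SD 0.3, peptide
counts 1 + Poisson(3) per cell, and 25% missing cells — chosen so that
per-disease quantification rates and per-cell peptide counts resemble a
real pooled experiment. Pooling of individuals is **not** simulated for
the discovery arm: the statistics operate on pool ratios, and pool-mean
convergence makes the individual level irrelevant to them. The
distribution of peptides per protein is not knowable from published
summaries; the shifted Poisson is a modeling choice exposed in the
configuration.

`elisa_sim_config()` emulates the replication arm: log-normal
concentrations with the case member shifted by `log(true_gmr)`;
duplicates are collapsed to one averaged value per sample (only
per-sample summaries are ever analyzed). Defaults use n = 106 pairs and
per-member log-SD 0.3, which reproduces the interval width scale of a
plasma immunoassay replication of that size (a reported GMR interval of
roughly 1.11–1.29 around 1.18 implies a within-pair log-ratio SD near
0.41, i.e. ~0.3 per member). Covariates are drawn per pair and applied
to both members, so they cancel in the ratio unless configured
`asymmetric`, which is how confounding scenarios are constructed.

What passing tests on these data do **not** show: robustness to
identification error, to correlated peptide interference, to
non-normal heavy-tailed ratio noise, or to informative missingness
(cells here go missing at random, while in MS data low-abundance
proteins drop out preferentially). Conclusions about real data inherit
those caveats.

## Numerical choices and degenerate inputs

* Rank deficiency is detected by QR on the weighted design; only the
  label covariate is ever dropped (disease means are always estimable
  from observed rows).
* `s2 = 0` cells (noise-free or constant data) are tolerated: zero
  variances are excluded from hyperparameter moment matching, and an
  all-equal variance vector returns `d0 = Inf` with `s0^2` the common
  value.
* Permutation exceedance uses a `1e-12` tolerance so the identity
  assignment is never lost to floating-point noise; ties count as
  exceedances (conservative).
* An all-zero set matrix has `T2 = 0` defined directly (its covariance
  plus ridge is singular only when the statistic is identically zero).
* Quartile cut points come from the pooled distribution with ties to
  the lower quartile; heavily tied data that cannot form four groups
  raise an error rather than silently collapsing categories.
* Missing values serialize as `NA`; all tables are tab-separated with
  headers and full-precision floats.

## Problem sizes used in the test suite

The suite favors a few deep, parameterised checks over many shallow
ones, at sizes chosen to keep the full run in tens of seconds: type-I
calibration pools ~4,000 null p-values from five 400-protein
experiments; hyperparameter recovery uses 5,000 simulated variances;
interval coverage uses 1,000 replicates of 60 pairs; sign-flip validity
uses 400 exact enumerations at 3x8; the set-test power check uses 60
replicates with a 0.5 log2-unit shifted set. Weighted least squares,
the 2x2 ridge statistic and the contingency-table odds ratios are
checked against closed-form oracles at machine precision.

## Known limitations

* No imputation at the quant stage (missing cells stay missing until
  set testing, where row-mean imputation is explicit and reported).
* Unconditional logistic regression only; matched sets beyond 1-1
  pairing are not modeled.
* The exact null requires exchangeable pool pairs within a disease;
  batch structure across experiments would need stratified flipping,
  which is not implemented.
* FDR alternatives beyond Benjamini-Hochberg (q-values, adaptive
  procedures) are out of scope.
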