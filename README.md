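# poolprot

Inference for pooled case-control plasma proteomics. When individual
samples are too numerous (or too precious) to profile one by one, equal
plasma volumes from ~100 cases and ~100 matched controls can be pooled,
isotope-labeled (heavy/light acrylamide on cysteine), mixed and analyzed
by LC-MS/MS: each pool pair yields one heavy/light peptide ratio table,
and a handful of pool pairs per disease supports protein-level inference
about case-control concentration differences. `poolprot` implements the
statistical pipeline for this design, end to end, plus the replication
statistics used to confirm candidates by immunoassay in individual
samples.

## The model

For protein group *g* and pool pair *i*, the rolled-up log2 case/control
ratio is modeled as

    y_gi = mu_g,d(i) + lambda_g * x_i + e_gi

where `mu_gd` is the disease-specific case/control effect,
`x_i = +1` when the heavy label was assigned to the case pool and `-1`
otherwise (so `lambda_g` absorbs any labeling bias), and the weighted
least-squares fit uses the number of quantified peptides behind each
`y_gi` as weights. Residual variances are moderated by empirical Bayes:
`s2_g` is shrunk toward a prior `s0^2` with prior degrees of freedom
`d0` estimated by digamma/trigamma moment matching across all proteins,
giving the moderated t-statistic

    t_gd = mu_gd / (u_gd * s_tilde_g),   s_tilde_g^2 = (d0 s0^2 + d_g s2_g) / (d0 + d_g)

on `d0 + d_g` degrees of freedom. P-values are adjusted per disease by
the Benjamini-Hochberg step-up rule. Protein sets (e.g. KEGG pathways
with >= 3 quantified members) are tested jointly by a regularized
Hotelling statistic `T2 = n ybar' (S + rI)^{-1} ybar` with ridge
`r = ridge_frac * mean(diag(S))`, against an exact sign-flip permutation
null over the pool pairs. Replication of a candidate in individual
matched pairs uses paired geometric mean ratios with t intervals,
covariate-adjusted log-ratio models, quartile logistic regression with a
trend test, and the projection of a fold-change `g` onto an odds ratio
`OR = exp(beta ln g)` from a logistic slope `beta` on log concentration.

Everything upstream of peptide heavy/light ratios (search engines,
protein grouping, peak-area extraction) is out of scope; protein group
ids are taken as given.

## Worked example

Step-up FDR on a published-style per-disease result table (37 proteins
listed, 346 tested), overlap with hormone-therapy effect tables, and a
fold-change conversion:

```r
library(poolprot)
chd <- read_diff_results(system.file("extdata", "chd_diff_example.tsv",
                                     package = "poolprot"))
fdr <- bh_adjust(chd$p, n_total = 346)
data.frame(protein = chd$protein, p = chd$p, fdr = signif(fdr, 3))[1:4, ]
#>   protein        p    fdr
#> 1     B2M 5.07e-05 0.0175
#> 2    ORM1 1.82e-04 0.0315
#> 3  IGFALS 3.84e-04 0.0443
#> 4   THBS1 1.33e-03 0.0751

ht <- read_ht_effects(system.file("extdata", "chd_ht_effects.tsv",
                                  package = "poolprot"))
cand <- select_candidates(chd, ht, p_thresh = 0.05)
nrow(cand)          # 18 proteins significant for disease and >= 1 therapy arm
cand[cand$protein == "B2M",
     c("protein", "log2_ratio", "p", "ep_log2", "ealone_log2", "concordant")]
#>   protein log2_ratio        p ep_log2 ealone_log2 concordant
#> 1     B2M      0.212 5.07e-05   0.208        0.23       TRUE

log2_to_fold(0.212) # 1.158: a 15.8% higher concentration in cases
```

Three proteins reach FDR < 0.05 for CHD; B2M is elevated both in future
cases and after either hormone-therapy regimen, which is what makes it a
candidate mediator. The same discovery machinery runs on synthetic pooled
experiments with known truth:

```r
delta <- numeric(60); delta[1:6] <- c(0.4, -0.4, 0.3, -0.3, 0.25, -0.25)
sim <- generate_pool_experiments(pool_sim_config(n_proteins = 60,
                                                 effect_log2 = delta,
                                                 seed = 9))
m <- center_by_experiment(rollup(sim$peptides))
fits <- fit_weighted_model(m)
hy <- estimate_hyperparams(fits)
res <- differential_results(fits, hy)
head(res[res$disease == "CHD", c("protein", "log2_ratio", "t", "p", "fdr")], 4)
#>   protein log2_ratio    t        p    fdr
#> 1   P0001      0.530 3.87 0.000363 0.0218
#> 2   P0023      0.383 2.54 0.015074 0.3712
#> 3   P0033      0.313 2.25 0.029739 0.3712
#> 4   P0029      0.396 2.24 0.031248 0.3712
```

The top-ranked protein is the one simulated with the largest true
effect. `run_pipeline()` chains all stages (simulate/quant/diff/sets/
overlap/replicate) from a single configuration and writes tab-separated
outputs plus a JSON run report.

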