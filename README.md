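# ecaccess

Travel time to emergency care and the severity of paediatric anaemia at
hospital admission.

## The problem

Blood transfusion — the life-saving intervention for severe childhood
anaemia (haemoglobin < 5 g/dl) — is typically available only at referral
hospitals. Children with mild or moderate anaemia can be treated at
lower-level facilities, but severe cases must travel. If long travel times
delay care-seeking, children from distal villages should present *more
severely ill* when they finally arrive. `ecaccess` is a research compendium
for testing that hypothesis: it models travel time from village-scale
enumeration areas (EAs) to a hospital over a raster friction surface,
builds an analysable admission cohort, and estimates the association
between travel-time class and severe (vs mild/moderate) anaemia with a
Bayesian spatial logistic model.

It is aimed at epidemiologists and health-geography researchers who want a
fully reproducible, tested implementation of this analysis chain — including
a synthetic data generator with known ground truth, since admission
datasets of this kind are rarely publicly deposited.

## The model

Travel time is the least-cost path on the 8-connected pixel graph of a
friction surface (seconds/metre from road- and land-cover-specific speeds;
water impassable), averaged per EA and classed into half-open 30-minute
intervals with `<30` min as reference. For admission *i* from EA *k*:

```
Y_ik ~ Bernoulli(pi_ik),   Y = 1 for severe anaemia
logit(pi_ik) = beta_0 + sum_j beta_j x_ij + omega(s_k)
```

with `omega` a zero-mean Gaussian process over EA centroids under the
Matérn covariance

```
C(h) = sigma^2 * 2^(1-nu)/Gamma(nu) * (kappa h)^nu * K_nu(kappa h)
```

Covariates (age, sex, nutrition, vaccination, malaria diagnosis,
sickle-cell disease, weekday, season, malaria endemicity PfPR, rurality)
pass a univariate logistic screen at p < 0.2. Inference is an exact-GP
Laplace approximation over EA centroids, with the coefficient posterior
integrated over a log-scale hyperparameter grid (a marginal-likelihood-
weighted Gaussian mixture), so credible intervals carry hyperparameter
uncertainty. Adjusted odds ratios (AORs) are exponentiated coefficient
quantiles. Descriptive layers include admission rates per 1,000 children
by 15-minute band (distance decay), Wilson intervals, Kruskal–Wallis and
Fisher tests, and crude odds ratios. See the methods vignette
(`vignettes/travel-time-anaemia.Rmd`) for the full account.

## Worked example

Reproduce the headline contingency analysis from a published severity-by-
travel-time table (counts: 302 severe / 403 other at 30–59 min vs 221 /
1,050 at <30 min), and the Wilson interval for the severe share within 30
minutes (221 of 634):

```r
library(ecaccess)
or <- crude_or(302, 403, 221, 1050)
sprintf("OR %.2f (%.2f-%.2f)", or$or, or$lower, or$upper)
#> "OR 3.56 (2.89-4.38)"
round(wilson_ci(221, 634), 4)
#>  lower  upper
#> 0.3125 0.3865     # prints as 34.9% (31-39%)
```

Run the whole pipeline on a synthetic region (80×80 pixels of 400 m, 60
EAs, 2,500 admission records; ~5 s on one CPU):

```r
cfg <- run_config(out_dir = "demo_run", seed = 1,
                  make_figures = FALSE, verbose = FALSE)
res <- run_pipeline(cfg)
res$ledger
#> Exclusion cascade:
#>   extracted (residents aged 1-59 m)   2500
#>   - cause-based exclusions             370
#>   - missing haemoglobin                116
#>   - not anaemic (Hb >= 10 g/dl)        700
#>   analysed                            1314
res$or_table
#>  tt_class   n   pct crude_or crude_lo crude_hi  aor aor_lo aor_hi
#>       <30 862 65.60       NA       NA       NA   NA     NA     NA
#>     30-59 268 20.40     4.34     3.19     5.89 2.59   1.30   5.21
#>     60-89 150 11.42     4.84     3.34     7.02 3.08   1.18   8.27
#>      >=90  34  2.59     5.05     2.51    10.16 2.54   0.75   8.54
```

The ledger is the audit trail of the exclusion cascade. The final table
shows, per travel-time class, admission counts, crude severe-vs-other odds
ratios against the `<30` min reference, and the spatially adjusted AORs
with 95% credible intervals — here recovering the generator's built-in
distance effect (truth AORs 2.44 / 3.55 / 3.41) from one modest synthetic
cohort. The output directory also contains the cohort and tables as CSV,
the fit as JSON, and a manifest with MD5 checksums of every file.

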