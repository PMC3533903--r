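# pcmreg

Latent regression Partial Credit Models for multi-item questionnaires,
with differential item functioning (DIF) detection and nonparametric IRT
checks.

## What problem this solves, and for whom

Population surveys that monitor health-related quality of life (e.g. with
the SF-36) need *measurement invariance* before group comparisons mean
anything: an item must work the same way for young and old, men and
women, 1995 and 2003. `pcmreg` is for biostatisticians and psychometric
analysts who want the full Rasch-family workflow for one questionnaire
dimension:

1. **DIF scan** — a Partial Credit Model (PCM) is fitted per population
   stratum by pairwise conditional estimation (trait-free, so group
   *impact* cannot masquerade as DIF); item locations are compared across
   strata by size-weighted ANOVA, and an item is flagged when the effect
   is significant at 5% *and* moves the location by more than 0.1 logits.
   Flagged items are split into group-specific **pseudo-items**.
2. **Assumption checks** — Loevinger scalability coefficients
   (pass when `H > 0.3`, `H_j > 0.3`, `H_jk > 0`) and a monotonicity
   `Crit` composite (acceptable below 40).
3. **Latent regression** — marginal ML calibration of the PCM with
   `Theta ~ N(0, sigma2)`, then a mixed PCM in which covariates explain
   both moments of the trait:

   ```
   P(Y_nj = y | theta) ∝ exp( y·theta − Σ_{l≤y} delta_jl )
   Theta_n ~ N(mu_n, sigma2_n),  mu_n = mu* + X_n β,  sigma2_n = sigma2* + Z_n γ
   ```

   with backward elimination (p ≥ 0.05 and no AIC increase), an integer
   recoding of age from its dummy coefficients, item-trait chi-square
   fit tests with `500/N` rescaling for huge samples, and the
   explained-variance rate
   `tau = 1 − (n−1−k)·sigma2 / ((n−1−k0)·sigma2_0)`.

A synthetic-data generator (`sim_config()`, `simulate_qol()`) emulates
the target surveys (26 388 persons; gender, seven age bands, nine French
regions, two survey years) with configurable DIF offsets and informative
missingness, and is the test bed for every estimator in the package.

## Worked example

Simulate a General-Health-like survey with an age-DIF item and run the
whole pipeline:

```r
library(pcmreg)

cfg <- sim_config(N = 6000,
  dif_offsets = list(list(item = "GH1", factor = "age_band",
                          levels = c("65-74", "75-84"), offset = 0.6)),
  seed = 42)
dat <- simulate_qol(cfg)
res <- run_pipeline(dat$responses, dat$covariates,
                    item_specs_from_bank(cfg$bank),
                    config = pipeline_config(min_stratum = 60), seed = 7)
print(res)
#> == Questionnaire analysis pipeline ==
#> persons: 6000 ; items/pseudo-items: 16
#> DIF flags stage 1: 2 ; stage 2: 4
#> Nonparametric IRT (Mokken) checks
#>          H    min_Hj   min_Hjk  max_Crit mhm_pass
#>  0.5392489 0.5370897 0.5246902 -11.85449     TRUE
#> PCM calibration (marginal ML, latent mean fixed at 0)
#>   n = 6000, items = 16, sigma2 = 1.8081, logL = -54392.21, AIC = 108914.43
#> Item-trait chi-square: total = 60.56, df = 144, p = 1 (n = 6000)
#> Explained-variance rate tau = 14.2%
```

The injected DIF is found, with the age bands partitioned so the shifted
old-age groups get their own thresholds:

```r
res$dif_stage1$report[res$dif_stage1$report$flag, ]
#>  item   factor      diff            p                                 grouping
#>   GH1 age_band 0.5849619 7.469020e-06  18-24+...+55-64 / 65-74+75-84
```

Reading the summary: the scale passes the Mokken gates (`H = 0.54`, all
item and pair coefficients above their cutoffs, worst `Crit = −11.9`,
well below 40); after pseudo-item expansion 16 items/pseudo-items are
calibrated; the full-sample chi-square detects the tiny residual misfit
that any N = 6000 survey shows, while the statistic rescaled to an
effective sample of 500 (shown) is benign; and the selected covariates
explain 14.2% of the latent-trait variance — close to the generating
structure, where age, gender, region and year drive the mean.

The package also ships the published estimates of a large French SF-36
survey analysis as worked-example inputs:

```r
f <- published_sf36_estimates("GH")$footers
tau_explained(f$sigma2_0, f$k0, f$sigma2, f$k, f$n)
#> [1] 0.1311744        # prints as the reported 13%

pf <- published_coef_vector("PF")
profile_deviation(pf, list(Ager = 10), list(Ager = 0))
#> [1] -5.96            # 75-84 vs 18-24 year-old men, Physical Functioning
profile_deviation(pf, list(Ager = 10, Women = 1), list(Ager = 0, Women = 1))
#> [1] -5.293           # same contrast for women (Ager + Women:Ager)

a <- published_sf36_estimates("PF")$age_trends
recode_age_quantitative(setNames(a$deviation, a$band))
#> Quantitative age recoding (slope -0.6 ):
#> 18-24 25-34 35-44 45-54 55-64 65-74 75-84
#>     0     1     2     4     6     8    10
```

See `vignettes/latent-regression-pcm.Rmd` for the model, the estimation
choices and the design decisions.

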