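---
title: "Latent regression Partial Credit Models for questionnaire surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent regression Partial Credit Models for questionnaire surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmreg)
```

## The measurement problem

Comparing health-related quality of life across regions, survey years, age
bands and genders requires *measurement invariance*: the questionnaire must
award the same latent score to two people with the same underlying health,
whoever and wherever they are. Classical sum scores offer no way to check
or repair this. `pcmreg` implements a Rasch-family workflow for ordinal
multi-item scales (its presets target the SF-36 General Health, Physical
Functioning and Mental Health dimensions) that

1. screens every item for differential item functioning (DIF) across
   gender, age, region and survey year,
2. verifies the nonparametric assumptions of item response theory,
3. absorbs detected DIF through pseudo-items, and
4. explains both the **mean and the variance** of the latent trait by
   covariates inside the measurement model.

## The measurement model

Responses $Y_{nj} \in \{0,\dots,m_j\}$ follow the Partial Credit Model
(PCM): given the person trait $\theta_n$ and item step thresholds
$\delta_{jl}$,

$$P(Y_{nj}=y \mid \theta_n) =
\frac{\exp\!\big(y\theta_n-\sum_{l\le y}\delta_{jl}\big)}
     {\sum_{c=0}^{m_j}\exp\!\big(c\theta_n-\sum_{l\le c}\delta_{jl}\big)}.$$

`pcm_prob()` evaluates this on the log scale with max-subtraction and is
stable for $|\theta|\le 40$. The *location* of an item,
$\bar\delta_j = m_j^{-1}\sum_l \delta_{jl}$, is the one-number difficulty
summary that the DIF scan compares across strata.

In the latent regression stage the trait becomes random,
$\Theta_n \sim N(\mu_n, \sigma^2_n)$, with

$$\mu_n = \mu^* + X_n\beta_\mu, \qquad
  \sigma^2_n = \sigma^{2*} + Z_n\gamma_{\sigma^2},$$

where the reference group (in the survey presets: men, youngest band,
Paris Basin, 1995) is absorbed into the intercepts. The variance uses the
**identity link** for fidelity to the reporting convention of such
analyses — coefficients are interpretable as additive variance changes —
at the price of a positivity constraint: `lrpcm()` pushes the optimizer
back with a quadratic penalty below a configurable floor (default
`1e-3`) and flags any fit whose optimum touches it (`boundary = TRUE`),
rather than silently reparameterising. A log-link alternative was
considered and rejected as a default because published effect sizes on
the variance scale would no longer be directly comparable.

## Estimation

**Pairwise conditional estimation (PCE).** `pce_fit()` estimates
thresholds from the conditional probability of each observed item pair
given its sum, which is free of $\theta$ — so the estimates do not depend
on the trait distribution, the property that makes stratum-wise DIF
comparisons legitimate. All unordered pairs are weighted equally, the
objective is minimised by BFGS with an analytic gradient from a start at
zero, and identifiability is fixed by summing *all* thresholds to zero
within each fit. Stratum locations are therefore relative quantities;
only contrasts of locations are meaningful, which is all the DIF ANOVA
uses. Categories observed by nobody are collapsed downward with a
recorded mapping and a warning — never silently.

**Marginal maximum likelihood.** `calibrate_pcm()` fits the PCM with
$\Theta \sim N(0,\sigma^2)$ (mean pinned at 0 for identifiability),
estimating thresholds and $\sigma^2$ jointly; the thresholds are then
frozen for every latent-regression fit, matching the two-stage reporting
convention. `lrpcm()` maximises

$$\log L = \sum_n \log \int \prod_j P(Y_{nj}\mid\theta)\,
\varphi(\theta;\mu_n,\sigma^2_n)\,d\theta$$

by Gauss–Hermite quadrature *centred on each person's prior*
($\theta = \mu_n + \sigma_n\sqrt{2}\,x_q$), an exact reparameterisation
that adapts node placement to heteroscedastic variances. Quadrature
error decays geometrically in the order: on the package's simulation
scenarios the fitted log-likelihood at order 41 changes by under
$10^{-4}$ when the order is doubled (asserted in the test suite), and
the default of 21 nodes — chosen for speed — carries a $\sim 10^{-3}$
absolute log-likelihood offset that moves coefficient estimates by only
a few $10^{-4}$. Persons sharing a covariate profile share a
quadrature grid, so factor designs cost little more than a single-profile
fit. Analytic gradients are used throughout; Wald standard errors come
from finite differences of that gradient (observed information).

**Backward selection.** `backward_select()` prunes the mean model first
and then the variance model, each round removing the least significant
removable term with $p \ge 0.05$ whose removal does not increase AIC.
Hierarchy is enforced: an interaction may leave before its main effects,
a main effect only once no retained interaction contains it. Ties are
broken by the largest p-value. AIC is $2k - 2\log L$ with $k$ the number
of free mean/variance parameters of the fit (thresholds are frozen and
excluded; only AIC *differences* within a frozen calibration matter).

**Explained variance.** With $\hat\sigma^2_0$ the trait variance of the
covariate-free calibration (a model with $k_0$ parameters — thresholds
plus the variance) and $\hat\sigma^2$ the variance of the homoscedastic
fit with the selected mean covariates ($k = k_0 +$ mean parameters),

$$\tau = 1-\frac{(n-1-k)\,\hat\sigma^2}{(n-1-k_0)\,\hat\sigma^2_0}.$$

`tau_explained()` applied to the published French SF-36 summaries
reproduces 13% (GH), 27% (PF) and 5% (MH).

**Quantitative age.** `recode_age_quantitative()` converts fitted age-band
dummy coefficients into small integer scores proportional to them: the
base unit is the smallest-magnitude nonzero coefficient divided by the
smallest multiplier (1–4) whose rounded scores reproduce the coefficient
ratios within 0.25 of a score unit. Published series are reproduced
exactly: (0, 1, 2, 4, 6, 8, 10) for Physical Functioning, (0, 1, 2, 3, 6)
for Mental Health, (0, 2, 12, 17, 24, 32, 40) for General Health. The
pipeline keeps the recoded model only if its AIC does not exceed the
dummy model's by more than a configurable margin (default 0).

## DIF detection

Stage 1 fits one PCE model per gender × age × year stratum and, per item,
a main-effects least-squares ANOVA of locations on the factors, weighted
by stratum size. DIF is *large* when the factor's F-test is significant
at 5% **and** the weighted factor-level mean locations differ by more
than 0.1 logits — the conjunction makes the scan robust to the enormous
power of large surveys. Flagged factors get their levels merged greedily
(adjacent levels for ordered factors, location-sorted otherwise) while
the within-group spread stays ≤ 0.1; a grouping that collapses to a
single group rescinds the flag. Stage 2 re-estimates locations per
region × year after expanding the stage-1 pseudo-items, pooling a split
item's pseudo-locations with observation-count weights. Treating
locations as ANOVA observations is deliberately approximate inference —
it reproduces the reporting practice the scan is modelled on; the
simulation suite checks its operating characteristics instead (pooled
false-flag rate ≤ 7.5% at nominal 5% under trait *impact* without DIF,
≥ 90% power for a 0.5-logit uniform shift), which is the property that
matters: impact (true group differences in the trait) must not
masquerade as DIF, because PCE locations are trait-free.

One caution the simulations make visible: under the sum-zero constraint
a genuinely DIF item drags the *relative* locations of the clean items
in affected strata, so secondary flags can appear next to a strong true
DIF. The pipeline reports all flags; judging which are primary remains
an analyst decision, as it is in practice.

## Nonparametric checks

`loevinger_h()` computes $H_{jk}$ as the ratio of the observed ML
covariance of an item pair to the maximum covariance attainable with the
same margins (the comonotone coupling), with $H_j$ and $H$ aggregating
numerators over denominators; pairwise-complete cases per pair. The scale
passes when $H > 0.3$, all $H_j > 0.3$ and all $H_{jk} > 0$ (strict).
`monotonicity_check()` groups persons by rest score (listwise complete
cases; adjacent scores merged to a minimum group size, default
$\min(N/10, 500)$), tests every ordered pair of groups for decreases of
each step-response function larger than 0.03, and summarises violations
in an MSP-style `Crit` composite (weights documented in the function's
help page). `Crit` is reported raw — with no violations and $H_j > 0.3$
it is negative — and values below 40 are conventionally acceptable. The
composite's exact numeric value is a documented package convention, not
a claim to reproduce any particular proprietary implementation.

## Model fit testing

`item_trait_chisq()` partitions persons into 10 near-equal class
intervals and compares summed observed with summed expected item scores,
standardised by the model score variance, giving
$\chi^2 = \sum_j \sum_g z_{jg}^2$ with $J\times(G-1)$ degrees of freedom.
Two constructions make this exactly calibrated, which the test suite
verifies at 500 null replicates: (i) expected scores, score variances
*and* the class intervals for item $j$ are taken under each person's
**leave-one-out posterior** (given their other items), so the item never
predicts itself through the trait estimate — plug-in at the full-data EAP
deflates the statistic by almost half, while full-data grouping inflates
it; and (ii) each item's overall location residual is projected out of
its $z$-vector, which is the component threshold estimation absorbs and
what makes $G-1$ (not $G$) the right df. One numerical trap is worth
recording: the leave-one-out log-likelihood must not be formed as
`total - item`, because the $10^{-16}$ cancellation residue orders
persons *within tied rest patterns by their own response* and visibly
biases the interval sums; the grouping variable is therefore rounded to
9 significant digits.

For very large surveys `rescale_statistic()` multiplies the statistic by
$N_0/N$ (default $N_0 = 500$), leaving df unchanged — an intentionally
conservative device that ignores small absolute misfit rather than a
second calibrated test.

## The synthetic-data generator

`sim_config()` defaults describe the survey pair the package's presets
target: N = 26 388 persons; gender 46.5/53.5; seven age bands with
frequencies chosen to match the reported mean age of about 47 years
(the bands' exact frequencies are not published); the nine regions at
their published frequencies; survey years weighted 13.9/86.1; a
five-item, five-category General-Health-like scale with locations spread
over about 1.7 logits (thresholds are not published; the spread mirrors
the reported match between item difficulty and trait ranges); and
mean/variance coefficients at the published General Health magnitudes.
Covariates are drawn independently across factors — real surveys
correlate age with year and region, so generator-based checks exercise
the estimators, not the surveys' joint covariate structure. DIF is
injected as a uniform threshold shift for selected factor levels;
informative missingness uses a logistic link on $-\theta$ with the
intercept calibrated to a target overall rate, reproducing the
observation that heavy nonresponse marks lower traits. Passing tests on
these data therefore demonstrate correct estimation under the model's
own assumptions, not robustness to local dependence, multidimensionality
or correlated covariates.

Simulation scales used by the test suite (chosen to bound Monte-Carlo
error, and stated here as the package's study sizes): threshold recovery
at N = 2000 with 20 replicates; latent-regression bias at N = 5000 with
50 replicates; DIF size at 6 strata × 250 persons with 200 replicates and
power at 6 × 3000 with 100; fit-test calibration at N = 2000 with 500.

## Degenerate inputs and numerical conventions

Out-of-range codes are rejected with the item and persons identified;
persons with no observed responses are dropped from fits (EAP returns
`NA`); unobserved categories collapse downward with a recorded mapping;
a single dichotomous item cannot be calibrated; empty strata are dropped
with a warning and failed stratum fits leave missing cells; exactly
constant location columns give p = 1 in the DIF ANOVA rather than 0/0;
fit-test intervals without observations drop out with their df. All
optimisations are deterministic (BFGS from fixed starts), so the whole
pipeline is a pure function of data, configuration and seed.

## Known limitations

The ANOVA-on-locations DIF test inherits its approximate inferential
frame; the `Crit` composite is a convention; the variance identity link
can hit its positivity floor for extreme covariate patterns (the fit is
then flagged invalid rather than repaired); pseudo-item expansion for an
item split on two factors duplicates its responses across the per-factor
sets (the cross-product option avoids this at the cost of thinner
cells); and the explained-variance rate compares homoscedastic variance
estimates, as its definition requires, so it understates what the full
heteroscedastic model captures.
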