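---
title: "Measuring spatial access to mammography and its predictive validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatial access to mammography and its predictive validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(floatcatch)
library(dplyr)
```

## The problem

Neighborhood access to screening mammography can be quantified in several
ways that are *not* interchangeable: travel time to the nearest facility,
facility density per eligible population, or gravity-type scores that
balance travel barriers against competition for capacity. floatcatch
implements nine such block-group-level measures, the statistical battery
for comparing them (rank correlation, chance-corrected agreement of
quartile classes, global and local spatial autocorrelation), and a
predictive-validity stage that asks which measures are associated with the
neighborhood odds of late-stage breast cancer at diagnosis. Because
registry microdata and historical facility files cannot be redistributed,
the package ships a seeded synthetic-geography generator, so every stage is
exercised end to end on data with known structure.

## The nine measures

With `t_kj` the network travel time in minutes from block group `k`'s
centroid to facility `j`, `S_j` the number of mammography machines at `j`,
and `P_k` the population of women aged 40 and above:

* **dst** — shortest travel time, `min_j t_kj`;
* **dst5** — mean of the five smallest `t_kj` (all reachable facilities if
  fewer than five);
* **des** — service density: machines reachable within the 30-minute
  catchment per 10,000 women 40+,
  `scale * sum_{j : t_kj <= T0} S_j / P_k`;
* **sau, sac, sa3q, sa3s, sa6q, sa6s** — two-step floating catchment area
  (2SFCA) scores. Step 1 gives each facility a machine-to-weighted-demand
  ratio `R_j = S_j / sum_{k : t_kj <= T0} W(t_kj) P_k`; step 2 sums the
  ratios back to block groups, `A_k = scale * sum_{j : t_kj <= T0}
  W(t_kj) R_j`.

The six 2SFCA variants differ only in the decay weight `W`:

```{r}
decay_presets()[c("SA3Q", "SA6S")]
```

`sau` uses `W = 1` (pure catchment overlap), `sac` a truncated Gaussian
normalized to 1 at `t = 0` and 0 at `t = T0`, and the four zonal schemes
use the stepwise weight vectors above: three 10-minute zones or six
5-minute zones, each in a quick-decay and a slow-decay version. Quick
decay always down-weights a given travel time at least as much as slow
decay, so it concentrates access near facilities.

Key numerical conventions, fixed so results are bit-stable:

* the catchment is inclusive (`t <= 30` minutes) and zones are half-open on
  the left, `((i-1)w, iw]`, with `t = 0` in zone 1;
* a facility whose catchment contains no population contributes nothing
  (reported via a message) rather than erroring — the analogue of a
  facility at the edge of a study area;
* scores are reported per 10,000 eligible women (`scale = 1e4`). The scale
  is cosmetic and configurable; it was chosen so synthetic score magnitudes
  land in the low tens, the range typical of metropolitan studies with on
  the order of a hundred machines per few hundred thousand eligible women;
* centroids and facilities snap to the nearest network node (Euclidean),
  with zero access time to the node. The snapping rule is this package's
  convention; source data rarely state one;
* with several facility-years of machine counts, density and 2SFCA scores
  are computed per year and averaged (machine fleets drift slightly over
  time); travel times use the year-invariant network.

A useful identity for testing: with `W = 1` and `scale = 1`, total
population-weighted access equals total machines at facilities with
non-empty catchments, `sum_k P_k A_k = sum_j S_j`. The test suite asserts
this on every random instance, along with exact agreement with a literal
triple-loop transcription of the two-step formulas.

## Worked example

```{r}
tt <- matrix(c(5, 25,
               15, 15,
               35, 5),
             nrow = 3, byrow = TRUE,
             dimnames = list(c("b1", "b2", "b3"), c("f1", "f2")))
two_step_fca(tt, machines = c(f1 = 1, f2 = 1),
             populations = c(b1 = 100, b2 = 100, b3 = 100),
             decay = decay_spec("none"))
```

By hand: facility f1 reaches b1 and b2 (200 women), so `R_1 = 1/200`;
f2 reaches all three (300 women), so `R_2 = 1/300`. Then
`A_1 = A_2 = 10^4 (1/200 + 1/300) = 83.33` and `A_3 = 10^4/300 = 33.33`
machines per 10,000 women. b3's facility-poor position (only f2, shared
with everyone) shows up as the lowest score even though its travel time to
f2 is the shortest in the table — exactly the competition effect density
and travel-time measures miss.

## The deprivation index

Neighborhood socioeconomic deprivation is the main confounder of the
access–outcome association. It is built from 21 census covariates spanning
education, occupation, housing, income/poverty, racial composition and
residential stability:

1. standardize the covariates and extract factors from the correlation
   matrix by the principal-factor method (unit prior communalities by
   default, the classic SAS-style principal extraction; squared multiple
   correlations via `priors = "smc"`);
2. retain factors with eigenvalue above 1 and varimax-rotate when more
   than one is kept (conventional defaults; the sources of such indices
   rarely state alternatives);
3. take the factor with the largest absolute loading on the
   below-poverty-line variable as the deprivation factor, sign-flipped so
   poverty loads positively;
4. select variables with `|loading| >= 0.60`. This cut cleanly separates
   the nine classically index-defining variables (unemployment, vacant
   housing, crowding, female-headed households, public assistance, no
   vehicle, no phone, poverty, percent non-Hispanic African American,
   smallest loading 0.62) from the rest (largest loading 0.59) in the
   reference loading set shipped as `reference_loadings()`;
5. assess internal consistency with Cronbach's alpha on the standardized,
   orientation-aligned items, and score each block group as the mean of
   the selected variables' z-scores (oriented by loading sign).

The z-mean composite was chosen over regression factor scores because it
is transparent, monotone in every item, and invariant to affine transforms
of the inputs; regression-method scores are still returned by
`fit_deprivation_factor()` for comparison. On synthetic single-factor data
both track the generating latent factor with correlation above 0.9.

```{r}
region <- generate_region(region_spec(n_blockgroups = 300, seed = 7))
covars <- generate_deprivation_covariates(region$blockgroups, seed = 7)
idx <- deprivation_index(covars)
idx$selected
round(idx$alpha, 2)
```

## Comparing the measures

* **Spearman correlation** of the raw scores (average ranks for ties).
* **Weighted kappa** of quartile classes: quartiles blunt the influence of
  skewness and prevalence on agreement. Cuts are type-7 interpolated
  quantiles, intervals closed on the right. Kappa uses linear
  (Cicchetti–Allison) disagreement weights `|i-j|` by default — the common
  epidemiological choice when only "weighted kappa" is specified —
  with quadratic weights behind a flag; confidence intervals come from a
  seeded percentile bootstrap (assumption-light, since the usual asymptotic
  variance formulas differ across software). Labels follow the Landis–Koch
  scale (slight/fair/moderate/substantial/perfect).
* **Global Moran's I** under inverse-distance weights (power 1, no
  cutoff, row-standardized: every unit influences every other, with
  influence fading by distance), with expectation `-1/(n-1)`, the
  randomization variance, and a symmetric normal-approximation CI.
* **Local Moran's I** (`I_i = z_i sum_j w_ij z_j / m2`) with conditional
  permutation pseudo-p-values (999 draws by default, no multiple-testing
  correction, matching common LISA practice; the observation's own value
  stays fixed while the others are permuted) and HH/LL cluster and HL/LH
  outlier classes by the quadrant of `(z_i, lag_i)` at `p < 0.05`. The sum
  of the local statistics equals `S0` times the global statistic — asserted
  exactly in the tests.

## Predictive validity

Cases (block group, age group `<50`/`50–64`/`65+`, race group
NH-White/African American/Other, late- vs early-stage indicator) are
modelled with multilevel logistic regression — cases nested in block
groups with a Gaussian random intercept, fit by Laplace-approximate
maximum likelihood (`lme4::glmer`). Exposures are dichotomized at the
overall median (below-median accessibility and above-median deprivation
are the indicator levels; ties go to the reference side). Model forms:

* **I** low accessibility + age; **II** + race; **III** + high deprivation;
* **joint** a four-level accessibility-by-deprivation classification
  (nonlinear combination effects);
* **stratified** form II within each deprivation stratum (interaction),
  using the overall accessibility median in both strata — the generating
  and analysis dichotomizations then agree, and strata remain comparable.

Odds ratios carry Wald 95% CIs on the log-odds scale; goodness of fit is
the deviance scaled by residual degrees of freedom. Setting
`random_intercept = FALSE` fixes the between-group variance at zero and
reduces the fit to ordinary logistic regression; the test suite requires
agreement with a direct `glm` fit to 1e-6 there, and recovery of a
generating odds ratio of 1.2 to within 0.05 on the log scale (mean of 100
replicates of 4,000 cases over 200 block groups, random-intercept SD 0.3).
For the travel-time measures (`dst`, `dst5`) larger values mean *worse*
access, so the validity stage flips their sign before the median split;
"low access" then has a consistent direction across all nine measures.

## The synthetic generator

`generate_region()` draws block-group centroids uniformly over a square
region (default 30 km side, 200 block groups) with lognormal women-40+
populations (log-mean 5.7, log-SD 0.5: median ≈ 300, heavy right tail —
a plausible urban block-group scale); facilities cluster around three
attraction centers with Gaussian scatter (SD = extent/10), mimicking the
concentration of services in commercial corridors; the road network is a
jittered lattice (or a nearest-neighbour-plus-spanning-tree random planar
graph) with edge times = length / 0.6 km-per-minute, giving 0–40-minute
travel times at the default extent. Machine counts are Poisson (mean 2,
floored at 1) with ±1 year-to-year perturbations at probability 0.1 over
5 facility-years. Deprivation covariates follow a single-latent-factor
model with the reference loadings and unit total variance; case outcomes
follow the logistic model above with default odds ratios of 1.2 for low
accessibility and high deprivation, a 40% baseline late-stage fraction,
random-intercept SD 0.3, and fixed (overridable) age/race marginals of
(0.25, 0.35, 0.40) and (0.60, 0.35, 0.05) — placeholders, as no public
joint distribution exists for a registry population.

What the generator deliberately does not emulate: real street topology,
geocoding error, spatially autocorrelated deprivation (the latent factor
is i.i.d. across block groups), facility quality differences, or
individual-level covariates beyond age and race. Green tests therefore
demonstrate that the estimators are implemented correctly and recover
known structure — not that any particular real region behaves this way.

## Reproducibility

`run_all()` executes simulate → travel → access → deprivation → agreement
→ spatial statistics → validity from one `run_config()`. Each stage's seed
is derived from the master seed and the stage name
(`stage_seed(master, name)`), so stages are reproducible independently of
execution order and a fixed master seed yields byte-identical CSV/JSON
output. Problem sizes used by the shipped test suite and acceptance script
(200 block groups, 20 facilities, 4,000 cases, 199 local-Moran
permutations, 200 bootstrap resamples) were chosen as the smallest
configuration at which every Monte-Carlo check is stable; all are config
options for larger runs.

## Known limitations

* The continuous decay parameter defaults to β = 15 minutes; the zonal
  weight vectors are treated as given constants rather than derived from a
  β, because stepwise published weights rarely document their generating
  curve.
* Inverse-distance Moran weights with no cutoff make the weight matrix
  dense; for regions beyond a few thousand units a threshold is advisable.
* The local-Moran permutation loop is exact but O(n² · n_perm); scale
  `n_perm` accordingly.
* Stratified validity models use the overall exposure median; re-splitting
  within stratum is a defensible alternative the package does not
  implement.
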