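---
title: "Subnational burden mapping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subnational burden mapping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`geoburden` estimates the subnational burden of childhood diarrhoea —
prevalence, incidence and mortality among children under five — from
cluster-level household-survey data, the way large model-based
geostatistics (MBG) studies do, and exercises the whole chain on synthetic
survey worlds whose truth is known. This vignette is the package's account
of the science: the model, its assumptions, the tunable parameters, what
the synthetic worlds do and do not emulate, and where design was genuinely
open.

## The estimation chain

1. **Survey data.** Observations are cluster-level binomial counts: of
   $N_c$ children examined in cluster $c$, $y_c$ had diarrhoea (three or
   more loose stools in 24 hours) at the survey moment. Some records carry
   only polygon (district) geometry; these are resampled into point
   pseudo-clusters.
2. **Covariate preparation.** Gridded covariates are standardized at
   generation; multicollinearity is filtered by iterated variance inflation
   factors at a threshold of 3.
3. **Stacked generalization.** Component learners (penalized logistic
   regression, a probability forest, a binomial GAM) are fit to the cluster
   data; their cross-validated predictions become the candidate covariates
   of the second stage.
4. **Geostatistical model.** A Bayesian hierarchical binomial model with a
   space–time Gaussian process produces joint posterior draws of the
   prevalence surface (250 by default).
5. **Post-estimation.** Prevalence converts to incidence via the mean
   episode duration (4.2 days), incidence to mortality via country–year
   case-fatality rates; all three measures are raked, per draw, to national
   envelopes.
6. **Aggregation and inequality.** Draws are population-weighted into
   admin units; uncertainty intervals are the 2.5th/97.5th percentiles
   across draws; inequality is summarized by deviations from the country
   mean and a population-weighted Gini coefficient; trends are classified
   by annualised change.
7. **Counterfactuals.** Averted deaths are attributed to risk-factor
   groups (WASH, child growth failure) under an independence assumption.

## The geostatistical model

The second stage is

$$y_c \sim \mathrm{Binomial}\!\left(N_c,\; \mathrm{logit}^{-1}(\eta_c)\right),
\qquad
\eta(s,t) = \sum_j w_j\,\mathrm{logit}\, g_j(s,t) + u(s,t) + \varepsilon,$$

where $g_j$ are the learner prevalence surfaces, the stacking weights $w$
lie on the simplex, $u$ is a zero-mean Gaussian process with separable
Matérn-3/2 (space) × AR1 (time) covariance, and $\varepsilon$ is an iid
nugget. Inference is a pluggable contract — anything that returns joint
draws of $\eta$ over the grid qualifies. The default scheme is an
empirical-Bayes Gaussian approximation, written for desk-scale grids:

* the latent field at the observed cell-years gets a Laplace approximation
  (Newton iterations on the binomial log-likelihood with the GP prior);
* GP hyperparameters are optimized (Nelder–Mead) against the Laplace
  marginal likelihood plus priors — log-normal on the range (centred on a
  quarter of the grid side), half-normal on the spatial and nugget
  standard deviations, uniform on the AR1 correlation;
* joint surface draws are exact conditional simulations from the fitted
  covariance, extended from the observation sites to every cell-year.

Three calibration components deserve explanation, because naive stacking
plus empirical Bayes demonstrably understates uncertainty:

* **Out-of-sample offsets.** The second stage is fit against the learners'
  *cross-validated* predictions at the data sites, while prediction uses
  the full-data surfaces. Fitting against full-data surfaces lets the
  first stage absorb part of the residual field and shrinks the estimated
  GP variance; the out-of-sample residuals carry the learners' honest
  generalization error.
* **Stage-one error variance.** The full-data learner surfaces are
  themselves estimates. Their error variance is estimated from the
  weighted mean-square discrepancy between full-data and out-of-sample
  stacked predictions at the data sites and added to the predictive
  variance of every surface draw (as an independent term; the true error
  is smoother than iid, which this approximates).
* **Hyperparameter mixing.** GP variance parameters are weakly identified
  from cluster-level binomial data (binomial noise on the logit scale at
  $N_c \approx 20$–100 dominates the latent signal). Conditioning on the
  MAP understates interval width, so draws are mixed over hyperparameter
  values sampled from a multivariate-$t_4$ approximation of the
  hyperparameter posterior (Laplace at the MAP; the heavy tails
  acknowledge the right skew of variance-parameter posteriors).

With all three in place, 95% intervals cover the true cell prevalence for
roughly 90–98% of cell-years across replicate simulated worlds at the
default desk scale (20×20 grid, 6 years, ~1500 clusters). Hyperparameter
uncertainty beyond the $t_4$ approximation, and skewness of the latent
posterior, are still ignored; both are visible only as the few points of
coverage that remain world-dependent.

A caveat worth stating plainly: when the flexible learners (forest, GAM)
dominate the stack, they can interpolate the spatial field through
covariate space, leaving a residual whose structure is no longer
stationary Matérn. Point predictions stay good, but single-world interval
coverage degrades (we have observed 0.7–0.9). This is a structural
property of stacked MBG, not of this implementation; the well-specified
configuration (penalized-linear first stage when the truth is
logit-linear) is what the package's calibration checks use.

## Stacking

Learners consume the covariates and emit probability predictions:

* *penalized-linear*: elastic-net logistic regression (`glmnet`) on the
  exact binomial likelihood (two-column count response). An earlier design
  fit a weighted Gaussian model to the empirical logit of cluster
  prevalence; at cluster sizes near 20 and prevalence near 5% the
  empirical logit is biased upward by ~0.17 on the logit scale, which
  propagated into biased surfaces — hence the exact-likelihood choice.
* *tree-ensemble*: a probability forest (`ranger`) on case/non-case
  expanded rows weighted by counts — robust to very unequal cluster sizes
  without assuming a rate-scale likelihood.
* *spline-additive*: a binomial GAM (`mgcv`) with thin-plate smooths per
  covariate, basis size capped for desk-scale speed.

Folds are whole survey sources (all records of a source share a fold),
mirroring source-stratified validation; stacking weights are estimated on
the simplex by maximizing the binomial likelihood of the simplex-weighted
out-of-sample logits.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_draws` | 250 | draws | joint posterior draws carried through all post-estimation |
| `duration` | 4.2 | days | mean episode duration for prevalence→incidence |
| `vif_threshold` | 3 | — | multicollinearity filter |
| `n_folds` | 5 | folds | source-stratified CV |
| UI percentiles | 2.5/97.5 | % | uncertainty intervals across draws |
| `change_threshold` | 0.10 | /year | "declining" classification (annualised) |
| `dominance_share` | 0.5 | — | dominant-driver labelling |
| `polygon_k` | 10 | points | pseudo-clusters per polygon record |
| Matérn smoothness | 3/2 | — | fixed: differentiable fields, closed form |

Raking is per draw (mean-only raking would distort intervals), on the
logit scale for prevalence (keeps probabilities in $[0,1]$; solved by
bisection to $10^{-10}$) and multiplicatively for incidence and mortality
(closed form). Countries can be excluded from raking, mirroring analyses
that distrust a particular national envelope. Case-fatality rates are
constant within country-year by construction; this is known to
*understate* subnational mortality inequality and is documented, not
corrected. The year is 365 days (the difference from 365.25 is < 0.07%).

## The synthetic worlds

`generate_world()` builds a rectangular grid partitioned into countries →
admin1 → admin2 as contiguous rectangular blocks (contiguity is all
downstream aggregation needs), a heavy-tailed lognormal under-5 population
(a few urban-like cells dominate counts, sdlog 1.3 around ~500 children
per cell), and smooth standardized covariate surfaces, some time-varying.
`simulate_truth()` realizes logit-prevalence exactly as intercept + Xβ +
GP + nugget with the separable Matérn×AR1 field drawn by Cholesky
factorization; the default intercept (logit 0.04) puts incidence near 3.5
episodes per child-year and mortality at a few deaths per 1000
child-years, the field's scale. Surveys are population-weighted cluster
samples within a source's country-year, binomial at the cell-year truth;
a fraction of sources report polygon geometry at the admin2 level, sampled
at the unit's population-weighted mean prevalence. National envelopes are
the truth's population-weighted aggregates perturbed by a known relative
factor, so raking has a verifiable target; CFRs are drawn per country with
a slow secular decline.

What the generator does **not** emulate: real country borders, DHS
sampling weights and survey design effects, seasonal recall structure,
age structure below five, and measurement biases of recall surveys.
Passing tests therefore demonstrate that the estimation chain recovers a
truth *of the assumed form* under realistic noise and coverage gaps — not
that any particular real-world figure is reproduced.

## Numerical choices and degenerate inputs

* Quantiles use linear interpolation between order statistics (type 7),
  both for UIs and for the published-style percentile examples.
* Cholesky factorizations add escalating jitter (from 1e-8) when a
  correlation matrix is numerically semidefinite.
* Largest-remainder rounding apportions children and cases over polygon
  pseudo-clusters (ties to the earlier cell); cases are capped at children
  per pseudo-cluster with deterministic forward redistribution; empty
  pseudo-clusters are dropped (totals conserved).
* VIF ties are broken alphabetically; a duplicated column therefore drops
  the alphabetically earlier name first. At least one covariate is always
  retained; constant columns report infinite VIF.
* All-zero outcomes fit without crashing: learners fall back to pooled
  rates, the GP intercepts near the boundary, predictions clamp to
  $[10^{-6}, 1-10^{-6}]$.
* Zero-population units aggregate to an undefined (NA) rate and zero
  count; zero baselines in trend classification are excluded and counted.
* `classify_change` defaults to annualised change, matching the
  "annualised decrease" convention of burden-mapping figure captions; the
  total-change reading of "greater than 10%" is available as a mode.
* The Gini is population-weighted across units (weighted across persons
  would require within-unit distributions the draws do not carry) and uses
  the sorted cumulative-share identity, checked against the $O(n^2)$
  pairwise form.

## Design choices that were genuinely open

* **Inference scheme.** The published analyses use a nested-Laplace
  package; the contract here (joint draws of $\eta$) is normative, and the
  implementation is an independent Laplace/empirical-Bayes scheme with the
  calibration components above. Exact numerical equivalence with any
  particular inference package is a non-goal.
* **Polygon integration.** Polygon records are resampled to
  population-proportional point pseudo-clusters (k = 10), matching the
  population-weighted logic of aggregation, rather than areal centroids.
* **Region structure.** All countries are fit jointly in one region at
  desk scale; per-region independent fits are a configuration loop, as is
  per-region VIF filtering.
* **ORS.** Treatment-group factors are excluded from the primary
  counterfactual (risk ratios for ORS efficacy are poorly pinned down);
  an inclusive mode exists behind a flag.
* **"101.4% of the national rate".** Deviation statements of this form are
  ambiguous between ratio 1.014 and relative deviation +101.4%; the
  deviation records carry absolute, ratio and relative forms so either
  reading is available.

## Problem sizes

The test-suite worlds are 4×4 to 20×20 grids with 2–6 years and up to
~1500 clusters; posterior sampling uses 100 draws mixed over 8
hyperparameter values. These sizes were chosen so a full check of every
stage, including the surface-recovery simulation, completes on a single
CPU in minutes while leaving the statistical conclusions (RMSE gain over
the best learner, interval calibration, raking exactness) stable.

## Known limitations

* Hyperparameter uncertainty enters through a parametric ($t_4$)
  approximation, not MCMC; extreme posteriors (tiny data) may be
  under-represented.
* The stage-one error term is iid on the logit scale, while true learner
  error is smooth in space.
* Dense conditional simulation scales as the cube of the number of
  cell-years; grids beyond a few thousand cell-years need a sparse or
  low-rank backend behind the same contract.
* The counterfactual's independence assumption (each risk factor acts and
  changes independently) is inherited from comparative-risk-assessment
  practice and is a stated limitation, as is the subnationally constant
  case-fatality rate.
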