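---
title: "Modelling thermal reaction norms for sex ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thermal reaction norms for sex ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsdnorm)
```

## The problem

In many reptiles the sex of an embryo is set by the temperature it
experiences during the thermosensitive period of incubation
(temperature-dependent sex determination, TSD). For the common TSD Ia
pattern, constant incubation at cool temperatures produces males and at warm
temperatures females. Two quantities summarise a population's pattern: the
**pivotal temperature** `P`, the constant temperature giving a 1:1 sex
ratio, and the **transitional range of temperatures** (TRT), the band of
temperatures producing mixed sex ratios, conventionally bounded at 5% and
95% male frequency. Throughout this package *sex ratio* means the relative
frequency of males among sexed embryos.

These parameters matter for conservation: a wider TRT means more
temperatures produce both sexes, which buffers a population against a
warming climate. Estimating them well from the small, unbalanced datasets
typical of incubation experiments (a handful of temperatures, few eggs,
often one or two mixed-sex groups) is the purpose of this package.

## Models

Two sigmoid families are supported.

**Logistic.** `sr(t) = 1 / (1 + exp((P - t)/S))`. `S` is one fourth of the
inverse of the slope at `P`; `S < 0` gives the falling TSD Ia shape. The
TRT has the closed form `|S * K_l|` with `K_l = |2 ln(l/(1-l))|`
(`l = 0.05` by default, so `K_l` is about 5.89).

**Flexit.** A four-parameter asymmetric generalisation evaluated piecewise
around `P`, with `K1` shaping the approach to the male asymptote and `K2`
the female asymptote (`sr_flexit()` documents the exact form). `S` is the
slope at `P` itself. With `K1 = K2 = 1` the flexit curve is exactly the
logistic with `S_flexit = 1/(4 S_logistic)` — note that `S` therefore means
*different things* in the two families, and the package converts only
explicitly, via `as_flexit_params()`. The TRT again has a closed form,
obtained by inverting each branch analytically; the signed expression is
negated for rising norms so the reported width is always positive.

Numerically, the flexit branches are evaluated in log space
(`log1p`/log-sum-exp identities). This matters because the binomial
likelihood is often nearly flat in `K2`: fitted values in the hundreds, with
standard errors in the thousands, occur in real data, and a naive
evaluation of `2^K - 1` would overflow long before that. `K` values below
`1e-9` in magnitude are replaced by `1e-9` with their sign kept, since the
form is undefined at `K = 0`; continuity across this substitution is tested.

## Data and filtering

A dataset is a tibble with one row per constant-temperature incubation
group: `temperature`, `amplitude`, `males`, `females`, `intersexes`, plus
label columns. The package ships the complete published incubation series
for olive ridley sea turtles (`olive_ridley()`: 40 groups, 277 males,
168 females, 19 intersexes, from beaches in three Regional Management
Units).

`filter_tsd()` applies two screening rules before fitting. Groups whose
recorded temperature amplitude exceeds 2 °C are dropped: even short
excursions to high temperature feminise a clutch relative to its mean
temperature, so such incubations are not "constant" in the relevant sense.
A *missing* amplitude is treated as "unknown, retain" — several published
groups print no amplitude yet are used in fits, and discarding them would
throw away a third of some datasets. Intersex embryos are excluded from the
analysable counts because the ovotestis classification is subjective; the
group itself is kept if sexed embryos remain. Both rules are logged
(`filter_report()`) and reconcile exactly: no embryo disappears silently.
A temperature correction factor column, where present, is carried through
but never applied.

## Maximum likelihood

Each group contributes a binomial term with the model's sex ratio at its
temperature; groups enter the likelihood exactly as listed (duplicate
temperatures are not pooled), and the binomial coefficient is included so
that reported `-ln L` values are comparable across software. `fit_tsd()`
minimises the negative log-likelihood with box-constrained L-BFGS-B
(`P` in [20, 40] °C, `S` in [-2, 2], `K` in [-1000, 1000]) from a grid of
starting points; candidate starts are pre-screened by objective value and
the best few optimised fully, with ties broken by the smaller
`|K1| + |K2|`. The flexit fit always runs the logistic first and seeds the
search at the equivalent flexit parameters — with the likelihood nearly
flat in `K2` a good start matters far more than optimiser polish.
Convergence is declared when a polishing pass improves the objective by
less than `1e-8`.

Standard errors come from inverting a central-difference Hessian
(per-parameter relative step `1e-4`, halved when an evaluation is not
finite); a singular Hessian falls back to a flagged pseudo-inverse.
Parameters with coefficient of variation above 1 are flagged: their sign is
not established by the data. A dataset with no mixed-sex group at all is
refused — an infinity of curves then share the maximum — with a pointer to
the Bayesian route, which handles that case honestly.

## Confidence intervals by resampling

`resample_fit()` draws parameter vectors from the asymptotic normal
(Cholesky factor of the covariance), discarding draws that flip the sign of
`S` — which would reverse the entire sex-determination pattern — or, for
flexit, of `K1 - 1` or `K2 - 1`. The delta method is deliberately *not*
provided: it assumes untruncated normality, which fails exactly for these
sign-constrained parameters. Screening is honest about its own bias: it
narrows the interval by construction (the caveat is attached to the
documentation, screening can be switched off, and a rejection rate above
90% triggers a recommendation to use MCMC instead). `ci_curve()` and
`ci_derived()` push each retained draw through the curve or through the TRT
closed form and report empirical quantiles.

## Goodness of fit

The deviance `D = 2(ln L_S - ln L_M)` compares the fit against the
saturated model (one parameter per listed group — adopting the per-row
convention keeps `df = n_groups - p` aligned with the published tables).
`D` is asymptotically chi-squared, but with 1–30 eggs per group that
asymptotics is unreliable: the null distribution of `D` sits far below its
degrees of freedom. `gof_null_deviance()` therefore simulates the null
honestly — redraw each group's male count from the fitted curve at the same
temperatures and egg numbers, refit, record the replicate deviance — and
reports the tail fraction (`>=` in the count). For well-specified data with
large counts the simulated null recovers the chi-squared mean, and the
p-value is approximately uniform; both properties are tested. The deviance
is clamped at zero (optimiser slop can make the identity marginally
negative), so a saturated-equivalent fit reports `p_random = 1` rather than
noise.

## Model and dataset comparison

`compare_models()` ranks fits of the *same* data by AICc
(`AIC + 2p(p+1)/(n-p-1)`) and Akaike weights `exp(-delta/2)`, normalised.
The sample size in the correction is the number of incubation groups as
listed. `compare_datasets()` asks a different question — one reaction norm
for a collection of datasets, or one each? — and uses BIC
(`-2 ln L + p ln n`), whose weight we call the *w-value* of a hypothesis.
Here the sample size follows a distinct-temperature convention: `n` is the
number of distinct temperatures after pooling duplicates
(`merge_temperatures()`), pooled-distinct for the grouped hypothesis and
summed per-dataset-distinct for the separated one. The two conventions are
deliberately not unified: each reproduces the corresponding published
table, and the choice is surfaced as an explicit `n_convention` argument
rather than hidden.

## Bayesian fitting

`fit_tsd_mcmc()` is a component-wise Gaussian random-walk
Metropolis–Hastings sampler on likelihood × prior. Priors follow a
five-field specification per parameter (density, two density parameters,
hard support bounds, start value, initial proposal sd); defaults put hard
support at `P` in [25, 35] °C, `S` in [-2, 2], `K` in [-500, 500], and — when
a maximum-likelihood fit is available — Gaussian priors centred on the
estimates with wide standard deviations (2 °C for `P`, 1 for `S`, 100 for
`K`) so the data dominate. Initial proposal sds are 2 for `P` and 0.5 for
the rest.

During the adaptation phase (first `min(10000, n_iter/2)` iterations)
proposal sds are rescaled after every batch of 100 iterations by
`exp(kappa (acc - 0.234))`, `kappa = 1/sqrt(batch)` — a Robbins–Monro
scheme targeting the optimal acceptance rate 0.234 — and frozen afterwards
so the summarised chain is Markovian. Burn-in defaults to 10 when starting
from the MLE and 10,000 otherwise. Posterior summaries use empirical
(type 7) quantiles with no thinning by default; the TRT is computed at
*every* retained parameter vector so its posterior honours parameter
correlations. A prior–posterior overlap diagnostic warns when a posterior
is essentially its prior (overlap above 0.9): such results describe the
prior, not the data.

The sampler accepts datasets the MLE refuses — all-male or all-female
series — because the posterior then correctly reports what such data
support: the prior, truncated by whatever the likelihood does exclude.

## The simulator

`simulate_tsd()` draws male counts binomially from any reaction norm on a
fixed design; it is the same generator the null-deviance test uses, and
`parameter_recovery()` wraps it into bias/RMSE/coverage studies with
per-replicate seeds derived from a master seed. The generator emulates the
binomial sampling structure of constant-temperature experiments only: no
temperature fluctuation within an incubation, no logger error, no clutch
effects (eggs within a group are exchangeable), no intersexes. Passing
recovery tests therefore validates the estimation machinery under the
model's own assumptions; it does not certify those assumptions for any
field dataset.

## Problem sizes used in the test-suite and worked analyses

The shipped analyses use the full 40-group dataset and its subsets as
published. Monte-Carlo components default to the published sizes (10,000
resampling draws, 1,000 null-deviance replicates, 100,000 MCMC iterations);
the package's own test-suite scales some property checks down (e.g. 120
recovery replicates, 40 coverage replicates at 6,000 iterations) — sizes
chosen so Monte-Carlo error stays well inside the asserted tolerances.

## Known limitations

* Only single-pivotal (TSD Ia/Ib) patterns: the two-pivotal female–male–female
  pattern of some crocodilians is out of scope, as are the Hill, A-logistic
  and Hulin sigmoid families.
* No multinomial treatment of intersexes: they are excluded, not modelled.
* No profile-likelihood intervals; the resampling and Bayesian routes are
  the two supported interval mechanisms.
* Field (natural-nest) temperature series are not handled: the reaction
  norm is defined by constant-temperature incubation only, and mean nest
  temperatures are a biased stand-in.
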