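---
title: "Effort-adjusted state-space models for count surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effort-adjusted state-space models for count surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Repeated point counts of vultures (or any conspicuous, mobile bird) at a
set of survey sites yield monthly count series that confound two sources
of variation: real fluctuation of the population using each site, and
noise in the counting process itself — birds missed, double-seen, or
misclassified, and surveys of unequal duration. `countssm` separates these
with a Bayesian state-space model and reports *relative abundance*: an
index comparable across sites and months, not an absolute census, because
detection is imperfect and only partially corrected (the model assumes
detection errors are equally probable everywhere).

## The model

For one species, sites $s = 1,\dots,S$ and months $t = 1,\dots,T$:

**Process.** Latent log-abundance follows a random walk with drift,
$$\log N_{t+1,s} = \log N_{t,s} + r_{t,s}, \qquad
  r_{t,s} \sim \mathrm{Normal}(\mu_r, \sigma_{\mathrm{proc}}^2),$$
where $r_{t,s}$ is the stochastic monthly change in abundance at site $s$
and $\mu_r$ is the mean monthly log-growth shared across sites.

**Observation.** Counts are Poisson with log-normal extra-Poisson noise
and a survey-effort covariate:
$$y_{t,s} \sim \mathrm{Poisson}(\lambda_{t,s}), \qquad
  \log \lambda_{t,s} = \log N_{t,s} + B\,x_{t,s} + \eta_{t,s}, \qquad
  \eta_{t,s} \sim \mathrm{Normal}(0, \sigma_{\mathrm{obs}}^2),$$
with $x_{t,s}$ the survey effort in hours, scaled and centered to mean 0
and sample SD 1 so the index refers to the mean time spent surveying.
This is the standard BUGS-style construction that separates process error
($\sigma_{\mathrm{proc}}$) from observation error ($\sigma_{\mathrm{obs}}$)
in count data and yields the error ratio
$\sigma_{\mathrm{obs}}/\sigma_{\mathrm{proc}}$ used as a model-adequacy
diagnostic.

**Priors.** Vague by default and user-overridable through `ssm_priors()`:
$\mathrm{Normal}(0, 10^2)$ for $\mu_r$, $B$ and each initial
log-abundance, $\mathrm{Uniform}(0, 10)$ for both SDs. These are diffuse
enough that the posterior is dominated by the likelihood; a frequentist
fit of the same model would give similar point estimates.

Species are fitted independently: the model pools nothing across species
except, optionally, the per-draw summation used for cross-species site
totals.

## Data preparation

Raw records are one row per site, station, survey date, 30-minute
interval and species. `collapse_station_counts()` applies the standard
point-count collapse:

1. within a station and survey, a species' value is the **maximum** over
   its 30-minute intervals (the largest number seen at once);
2. stations within a site combine by **maximum** by default — the
   conservative choice against double counting birds visible from several
   vantage points; `aggregation = "sum"` is available where stations are
   known not to overlap;
3. several surveys of one site in a calendar month collapse by maximum,
   since each site is covered within every month;
4. site-month effort is the total duration in hours of that site's
   sessions in the month; a session's duration is the maximum over its
   stations (observers count simultaneously). Effort must be recorded
   consistently within a station-survey; conflicting values are an error.

A site-month with no survey stays `NA` — zero is an observation, absence
of a survey is not — and contributes nothing to the likelihood. If all
recorded efforts are equal the standardized covariate is undefined
(zero sample SD); the dataset is then flagged and model fits drop the
effort term by fixing $B = 0$ rather than failing.

## Inference

`ssm_fit()` runs an adaptive random-walk Metropolis-within-Gibbs sampler
(compiled C++) over scalar blocks: each initial log-abundance, each
$r_{t,s}$, each $\eta_{t,s}$, $B$, and the two SDs on the log scale with
the appropriate Jacobian. Two details matter for mixing and correctness:

* $\mu_r$ has a conjugate normal conditional given the $r$ field and is
  drawn exactly.
* Both SDs also receive an *interweaved non-centered* update: the SD and
  its deviation field are rescaled jointly, holding the standardized
  residuals fixed. Centered scalar updates alone cross the ridge between
  an SD and the magnitude of its deviations slowly; the interweaved move
  traverses it directly and is what keeps $\hat R$ for
  $\sigma_{\mathrm{proc}}$ near 1 at desk-scale schedules.

Proposal scales adapt in batches of 50 iterations toward roughly 44%
scalar acceptance, only during the first `n_adapt` iterations; the
retained chain is therefore a valid Markov chain. Chains start from
overdispersed values; SD starts are drawn inside their uniform prior
support (a start outside the support would leave the support check with
nothing to accept). All randomness flows through R's RNG from a single
integer seed, so every run is exactly reproducible.

Two schedules ship with the package:

| schedule | chains | iterations | burn-in | adapt | thin | retained/chain |
|---|---|---|---|---|---|---|
| `"full"` (default) | 3 | 300,000 | 150,000 | 20,000 | 50 | 3,000 |
| `"desk"` | 3 | 20,000 | 10,000 | 5,000 | 10 | 1,000 |

The survey-scale default mirrors the schedule used for a full field
dataset. The desk schedule is the package's choice for simulation
studies, tests and examples: at the study dimensions (11 sites, 12
months) it converges (all $\hat R < 1.1$) in a few seconds per species,
and its 3,000 pooled draws give stable 2.5/50/97.5 percentiles. The
desk adaptation length is 5,000 because the survey-scale 20,000 would
exceed its iteration count.

## Diagnostics

* **Convergence**: the classical Gelman-Rubin statistic
  $\hat R = \sqrt{\{(n-1)/n \cdot W + B/n\}/W}$ per parameter on the
  retained draws, with convergence declared when all $\hat R < 1.1$;
  a split-half variant is available for trend detection, and trace
  export/plots support visual checks.
* **Adequacy**: the posterior distribution of the error ratio
  $\sigma_{\mathrm{obs}}/\sigma_{\mathrm{proc}}$, reported as the exact
  fraction of pooled draws above 10. The shipped rule flags the model
  "adequate" when that probability exceeds 0.90, i.e. when the counts are
  dominated by observation noise rather than process variation. The
  convention is reported together with both the probability and the flag
  so users can apply the opposite reading — large observation error as a
  *warning* — which parts of the literature prefer.

## Summaries

All reported quantities are medians with 2.5th and 97.5th percentiles,
computed by linear interpolation between order statistics (R's default
quantile type 7; the convention is pinned by tests). Per-species
abundance pools latent $N_{t,s}$ over all sites, months, chains and
draws; per-site abundance pools within site. Cross-species site totals
sum latent abundance across species *per retained draw* before
summarizing — the median of a sum is not the sum of medians. Species
fitted separately are paired draw-by-draw in chain order and truncated
to the shortest draw count. Whether to pool latent abundance $N$ (the
default) or expected counts $N e^{Bx+\eta}$ is exposed as a flag; latent
abundance is the quantity the process model describes.

## The synthetic-data generator

`simulate_counts()` forward-simulates exactly the model above, so it is
both a test harness and a power-analysis tool. Defaults mirror the study
design the package targets: 11 sites followed for 12 monthly surveys,
7 analyzable vulture species, session effort drawn uniformly on 2-4
hours, $\mu_r = 0.02$, $\sigma_{\mathrm{proc}} = 0.2$,
$\sigma_{\mathrm{obs}} = 0.3$, $B = 0.3$. Initial log-abundances default
to $\mathrm{Normal}(\log 8, 0.7^2)$ per site and species — a median of
about eight birds per site, the scale of the more abundant species in
such surveys, with realistic cross-site spread. Ground truth (latent
states and generating parameters) is returned beside the dataset but
never written into the observable CSV, so recovery tests cannot leak.

What the generator does *not* emulate: spatial covariance between sites,
seasonal detectability or effort patterns, observer heterogeneity, and
species misidentification. Passing recovery tests therefore show the
inference machinery is correct *under the model's own assumptions*; they
do not validate those assumptions against real field data.

`simulate_respondents()` generates the questionnaire side: 300
respondents (one adult over 16 per household), gender, education
(formal/nonformal, with formal education more frequent among men and
younger respondents), ages from a discretized log-normal per education
group truncated at 17 (medians 31 and 44 by default — only medians are
identified by the report shape, and the long right tail is
demographically plausible), and binary yes/no responses with per-group
probabilities (e.g. 98-99% have seen wild vultures, 3-9% a nest, 1-4%
are aware of diclofenac).

## Questionnaire statistics

Binary responses are compared with a **two-tailed Fisher exact test**
implemented by full hypergeometric enumeration over the feasible cell
range, with the sum-of-small-probabilities two-tailed rule (all tables no
more probable than the observed one, relative tolerance $10^{-7}$ for
floating ties) — the convention of `fisher.test` in R. Probabilities are
computed through log-binomial coefficients, so margins in the hundreds
(questionnaire scale, $n = 300$) remain exact; no chi-square fallback is
used or needed. A zero row or column margin makes the test degenerate:
$p = 1$, flagged.

Numeric responses use the **Kruskal-Wallis rank test** with mid-ranks,
the tie correction $1 - \sum(t^3 - t)/(N^3 - N)$, and a chi-square
reference with $k - 1$ degrees of freedom. If every observation is
identical the tie correction divides by zero and the statistic is
undefined; this is an error, not a silent $p = 1$. The chi-square
reference is an approximation: against the exact permutation
distribution its p-value can differ by well over 0.05 when groups are
very small (under about eight observations per group the permutation
distribution is too coarse), and the tests document this convergence
rather than pretending small-sample exactness.

## Numerical and design choices

* Sample SD (denominator $n-1$) for effort standardization; a degenerate
  (constant) effort covariate raises an error at the standardization
  level and drops to $B = 0$ at the model level.
* SDs are sampled on the log scale; uniform prior support is enforced by
  rejection, and the Jacobian term is included.
* Draw pairing for cross-species totals: by (chain, retained index),
  truncated to the shortest; conservation of per-draw sums is exact up
  to floating-point associativity ($10^{-9}$ in tests).
* One user seed fans out deterministically to per-stage child seeds
  (simulation, respondents, chains), all within 32-bit range, so stages
  are individually reproducible without seed collisions.
* The site/station hierarchy accepts both readings of a vantage-point
  design (stations nested in sites); the collapse rule is identical
  either way, and aggregation across stations is the user's call
  (`max` default, `sum` optional).

## Limitations

Relative abundance here is an index: it corrects for effort and
separates observation noise, but not absolute detectability, so values
are comparable across this study's sites and months rather than across
studies. Species observed only a handful of times carry almost no
information about $\sigma_{\mathrm{proc}}$ versus $\sigma_{\mathrm{obs}}$;
`ssm_fit_all()` skips species below a count threshold (default 3) for
this reason. The error-ratio adequacy rule is a convention, not a test
of fit; posterior-predictive simulation (`simulate()` on a fitted model)
and Pearson residuals are provided for genuine model criticism.

## A worked example

```{r, eval = FALSE}
library(countssm)

sim <- simulate_counts(sim_params(seed = 1))   # the default 11 x 12 x 7 design
fit <- ssm_fit(sim$data, species = "Egyptian Vulture",
               control = ssm_control(schedule = "desk", seed = 1))
summary(fit)
species_relative_abundance(fit)
site_relative_abundance(fit)
effort_coefficient_summary(fit)

resp <- simulate_respondents(respondent_sim_params(seed = 1))
survey_test_table(resp)
```
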