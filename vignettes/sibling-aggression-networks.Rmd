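---
title: "Dynamic sibling-aggression networks and food allocation: methods"
author: "kitepeck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic sibling-aggression networks and food allocation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kitepeck)
```

## The scientific problem

In facultatively siblicidal raptors such as the red kite (*Milvus milvus*),
eggs hatch asynchronously: in broods of three the first two nestlings hatch
nearly together while the junior can trail the middle one by up to four days.
The resulting age hierarchy shapes who attacks whom and who gets fed. Three
canonical down-rank aggression patterns are distinguished in the behavioural
literature:

* **close competitor** — attacks concentrate on similar-aged peers,
* **downward heuristic** — attacks run down the hierarchy in proportion to
  opportunity,
* **bullying** — attacks concentrate on the lowest-ranked sibling.

`kitepeck` implements a dynamic, network-style analysis of nest-camera event
logs that asks (i) whether the daily choice of attack recipient deviates from
chance, (ii) how that deviation moves along the sibling age-difference axis
with daily food delivery and nestling phase, and (iii) how aggression
patterns translate into the partitioning of parental feeding bouts among the
senior (S), middle (M) and junior (J) nestlings.

## The tendency-to-peck statistic

The unit of analysis is the brood-day. For each brood-day and each ordered
pair of nestlings (six directed dyads in a triad) we count pecks delivered
inside the 08:00–14:00 observation window. The null model randomly
reallocates every peck's recipient within the attacker's pool of possible
recipients — the actual recipient or the attacker's other sibling — keeping
attacker identities and daily totals fixed. The *tendency to peck* is

> deviation = observed count − mean count over recipient permutations,

positive when a recipient is targeted beyond its availability, negative when
it is avoided. In a brood of three the pool always has two members, so the
permutation expectation has the closed form `row_total / 2`; the Monte Carlo
estimator (default 10,000 permutations, per-event redraws) is validated
against this closed form in the test suite and conserves attacker-day totals
exactly by construction. Monte Carlo and closed form are kept as two separate
code paths precisely so the former can be checked against the latter.

Brood-days with zero pecks are retained as flagged all-zero records but are
excluded from model fitting by default (`include_zero_days = FALSE`): a day
without aggression carries no information about recipient *choice*. Retaining
them shrinks fitted curves toward zero; both paths are available and logged
in the run manifest.

## Smooth models and the bootstrap

The deviation is modelled as a Gaussian response on a tensor-product
penalized-spline surface of the dyad's signed age difference (hatch date of
attacker minus recipient; negative = attacker older) and the day's delivered
biomass, separately per phase, with the brood as a penalized random
intercept (`mgcv::gam`, REML):

```
deviation ~ phase + te(delta_days, biomass_g, by = phase, k = c(5, 5)) +
            s(brood_id, bs = "re")
```

Phase 1 covers junior ages 1–10 d (the vulnerable window), phase 2 ages
11–20 d; day 10 belongs to phase 1. Two models are fitted, for dyads whose
attacker is the older (negative age differences) and the younger (positive)
of the pair, because behaviour need not be continuous through zero. An age
difference of exactly zero is assigned by hatch rank: the earlier-ranked
nestling is treated as the older one. A basis dimension of 5 per marginal is
the default; it shrinks automatically when fewer distinct age differences
exist, and the surface degenerates gracefully to a curve in the age
difference when biomass is (near-)constant.

Uncertainty comes from the data-splitting bootstrap: 80% of the peck events
are drawn without replacement, the whole pipeline (counting, permutation
expectation, model fit) is rerun, and the split is redrawn 100 times (25 in
reduced test runs). Curves are reported as the pointwise mean and 2.5/97.5
percentile of the bootstrap predictions at the minimum, median and maximum
biomass observed over the modelled brood-days of that side, on an integer
age-difference grid spanning the observed range. Percentiles use R's default
linear order-statistic interpolation.

### Classifying patterns, and a calibration note

`classify_pattern()` reduces an attacker-older curve to one of the three
canonical labels (or `mixed`): *close competitor* when the curve is credibly
above zero at small |age difference| and credibly below zero at the most
negative one; *downward heuristic* when it is zero-consistent everywhere;
*bullying* when it is credibly positive only at the most negative age
difference.

"Credibly" deserves care. A percentile interval over refits on a fixed 80%
fraction *f* of the events is not a confidence interval for the zero-test:
without-replacement subsampling gives the refitted predictions a spread of
about `sqrt(f(1-f))` standard errors around (a scaled version of) the
full-data estimate, whereas a calibrated test against zero needs `f` of one.
Used raw, the interval falsely excludes zero at roughly a third of the grid
points even when recipients are chosen exactly at random — every
uniform-recipient dataset would be labelled as patterned. The classifier
therefore widens the interval about its bootstrap mean by the standard
m-out-of-n subsampling factor `sqrt(f/(1-f))` (= 2 at the 80% split) before
comparing against zero. The labels are additionally whole-curve decisions —
"zero-consistent everywhere" is an intersection over every grid point — so
the zero-test controls the family-wise error across the grid with a
Bonferroni widening (`qnorm(1 - 0.025/m)/qnorm(0.975)` for m grid points);
pointwise bands would misclassify a growing fraction of truly random curves
as the grid grows. The *emitted* curves keep the plain percentile
interval, so plots and tables show the bootstrap spread itself; only the
discrete labelling applies the calibration. With it, simulated
uniform-recipient colonies are labelled `downward_heuristic` and simulated
close-competitor colonies `close_competitor` in ≥90% of replicates (the
recovery checks in `tests/testthat/test-acceptance.R` compute these rates).

The estimation backend is penalized likelihood rather than MCMC; bootstrap
intervals replace posterior credible intervals, and coefficient-level
posterior summaries are declared out of scope. Direction and shape of the
effects are the reproducible quantities.

## Biomass

Each prey delivery contributes the observer's visual mass estimate when one
was recorded, otherwise the category mean whole-item mass times the
delivered fraction (whole, half, quarter). Category means are site-specific
field calibrations, so they are a required configuration input
(`weights.yaml`); the packaged example file contains synthetic illustrative
values. When the `unclassified` category has no configured weight it
defaults to the plain mean of the configured category means — a deliberate,
logged convention, since no principled weighting is available. An unrecorded
fraction defaults to 1 (conservative, flagged in the validation report).
Daily biomass is the sum over the brood-day's deliveries; deliveries carry a
date but no time, so the daily total is window-independent.

## Food allocation

The daily *peck log-ratio* `log((received_M + c)/(received_J + c))` (c = 0.5,
the Haldane–Anscombe correction, keeping zero days finite and symmetric)
summarises the prevailing aggression pattern: positive when the middle
nestling absorbs most attacks (close-competitor-like), near zero or negative
when attacks spread down the hierarchy. Which nestling receives each feeding
bout (bouts are scored until the oldest nestling is 21 d old) is modelled as
a multinomial additive logit regression with baseline S:

```
bout recipient ~ s(biomass_g, k = 4) + s(log_ratio, k = 3) +
                 s(age_S, k = 5) + s(brood_id, bs = "re")
```

The basis dimensions for biomass and log-ratio follow the analysis design
this package implements; the age smoother (a control for age trends in
provisioning) uses k = 5, and information-criterion-based knot selection is
deliberately out of scope. Predicted shares are population-level (random
intercepts excluded), non-negative and sum to one by construction; grids run
over one covariate with the others held at their observed means, at a fixed
age of the oldest nestling, and extrapolation beyond the observed range
warns rather than errors. The 95% bands attached to the share curves are
simulation bands from the Gaussian approximation to the penalized-likelihood
posterior of the coefficients (draws from `N(coef, Vp)` pushed through the
inverse multinomial link) and are labelled as such — the uncertainty
construction for allocation share curves is a package choice, made explicit
because no single canonical construction exists for this model.

## The synthetic-brood generator

Field event logs are not redistributable inside a package, so every pipeline
stage is exercised against a generator that emulates the statistical
structure the analysis assumes:

* **Hatching asynchrony** — S–M gap uniform on {0, 1, 2} days, M–J gap
  uniform on {1, …, 4} days (the up-to-96-h last interval), ranks by hatch
  order.
* **Provisioning** — daily biomass is stationary lognormal AR(1)
  (defaults: mean 90 g/day, sdlog 0.5, lag-1 correlation 0.3), emulating
  patchy scavenging opportunities. Preset colonies use 45 g ("paper_low_food")
  and 150 g ("paper_high_food") means, spanning the 73–120 g/day range
  typical of field phases.
* **Aggression** — per attacker-day Poisson counts with rank- and
  phase-specific base rates (phase 1: S/M/J = 170/32/1.4 pecks/day; phase 2:
  32/31/2.6), calibrated so a phase-1 brood-day totals ≈ 200 pecks and a
  phase-2 one ≈ 65 with the senior-to-middle dyad dominant — an
  order-of-magnitude calibration, not ground truth — and a mild positive
  food-rate coupling `(biomass/mean)^0.15`.
* **Recipient choice** — close competitor: probability proportional to
  `exp(-|Δage|/τ)` with τ = 1 d; downward heuristic: uniform over the
  two-sibling pool (in a triad, opportunity-proportional down-rank attack is
  indistinguishable from the permutation null, which is exactly the
  behavioural signature the label describes — note this deliberately reads
  "uniform over the pool", not "uniform over younger siblings", since a
  middle nestling restricted to its single younger sibling would produce
  strong nonzero deviations and a bullying-like signature); bullying: 90%
  of each attacker's pecks on the youngest available sibling.
* **Feeding bouts** — daily counts Poisson(0.8 × biomass); recipients drawn
  from share functions anchored at senior-skewed splits under poor food
  (S/M/J ≈ 0.40/0.47/0.14), a senior majority at average food
  (0.50/0.37/0.13) and a steep junior rise under rich food (junior ≈ 0.34),
  interpolated on the standardized log-biomass axis, with small brood-level
  logit shifts (sd 0.15) and a regime-specific junior shift.

All randomness flows from one master seed through named per-brood
sub-streams, so fixtures are bitwise reproducible. What the generator does
*not* emulate: parental arrival processes and within-day timing structure
(timestamps are uniform in the window), escalation dynamics within battles
(pecks are exchangeable within a day), growth and energetics, day-level
behavioural heterogeneity beyond the biomass process, and observation error.
Passing recovery tests therefore demonstrate that the pipeline identifies
the structures it models when those structures are present — not that field
data satisfy the generator's assumptions.

## Numerical and design choices

* Observation window half-open `[08:00, 14:00)` — no double counting at the
  boundary.
* Ages in integer days with hatch day = 0; phase from the junior's age;
  day 10 → phase 1, day 11 → phase 2.
* Broods with size ≠ 3 are dropped with a warning (the two-recipient pool
  and its binomial oracle are triad-specific; larger groups are out of
  scope).
* The deviation is the raw difference observed − expected, not standardized.
* Battle filter: a peck opens a battle when no earlier peck of the same
  ordered dyad occurred strictly within the gap (default 60 s, a construct —
  the data do not delimit battles); gap 0 disables the filter.
* Bootstrap sampling unit is the peck event (the atomic datum); exact subset
  size `floor(0.8 N)`.
* The peck log-ratio uses window-filtered pecks, consistent with every other
  peck statistic.
* Tied S/M hatch dates can optionally be relabelled at random (seeded), the
  preprocessing used when the two oldest are visually indistinguishable.
* Food terciles in network summaries are within-phase thirds of the
  brood-day biomass distribution, boundary days falling in the lower class.
* Reduced problem sizes used by the packaged checks (12 broods × 20 days,
  500 permutations, 25 bootstrap iterations, 20 replicates per regime) are
  the package's chosen desk-scale study conditions; the full-scale defaults
  (10,000 permutations, 100 iterations) remain the function defaults.

## Known limitations

* Triads only; generalizing the recipient pool breaks the binomial oracle
  and is future work.
* The classifier's calibration assumes the dominant noise is event-level;
  strong day-level behavioural heterogeneity would require a day-level
  resampling unit instead (available behind `bootstrap_splits`' inputs by
  passing day-subset data).
* Coefficient-level uncertainty from the original Bayesian estimation is not
  reproduced — only curve shapes, directions and classifications.
* The biomass weight table is user-supplied; results scale with it where
  observer estimates are missing.
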