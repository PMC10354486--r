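# kitepeck

Dynamic sibling-aggression networks and food allocation in asynchronously
hatching broods of three.

## What it is for

In raptor broods that hatch asynchronously, an age-based hierarchy decides
who pecks whom and who gets fed, and both can shift from day to day with the
food delivered to the nest. `kitepeck` turns nest-camera event logs (pecks,
feeding bouts, prey deliveries, hatch dates) into:

* a permutation-null **tendency to peck** — the deviation of each directed
  dyad's daily peck count from its expectation under random recipient
  reallocation. In a brood of three every attacker has a two-sibling
  recipient pool, so the null expectation is `row_total / 2`; the Monte
  Carlo estimator (default 10,000 recipient permutations) is validated
  against this closed form and conserves attacker-day totals exactly;
* **smooth curves** of that deviation against the dyad's signed age
  difference (negative = attacker older), by post-hatching phase (junior age
  1–10 d / 11–20 d) and daily delivered biomass, from tensor-product
  penalized splines with a brood random intercept (`mgcv`), refitted on 100
  bootstrap 80% splits of the events to yield pointwise mean and 95%
  percentile bands at poor / average / favourable (min / median / max)
  biomass;
* a **pattern label** per curve — `close_competitor` (similar-aged peers
  targeted, much-younger sibs avoided), `downward_heuristic`
  (zero-consistent everywhere, i.e. attacks proportional to opportunity),
  `bullying` (only the youngest targeted), or `mixed` — using a
  subsampling-calibrated zero-test (see the methods vignette);
* a **multinomial additive model of food allocation**: which nestling
  (senior S / middle M / junior J) receives each parental feeding bout, as
  smooth functions of daily biomass (k = 4), the daily log peck-ratio
  `log((pecks received by M + ½)/(pecks received by J + ½))` (k = 3) and the
  age of the oldest nestling, with a brood random intercept; predicted
  shares are non-negative and sum to one;
* a **synthetic-brood generator** with preset scenarios
  (`paper_low_food` = close-competitor aggression under poor provisioning,
  `paper_high_food` = opportunity-uniform aggression under rich
  provisioning, `bullying`) so the whole pipeline is testable without field
  data.

## Worked example

```r
library(kitepeck)

ds <- simulate_dataset(make_scenario("paper_low_food", n_broods = 6), seed = 42)
ds
#> <kite_dataset>
#>   broods:     18 nestlings in 6 brood(s)
#>   pecks:      16066 events
#>   bouts:      3760 events
#>   deliveries: 354 events
#>   validation: 0 flagged row group(s)

res <- run_tendency_pipeline(ds, n_perm = 1000, n_boot = 25, seed = 42)
res$patterns
#>   phase biomass_level          pattern
#> 1     1           max close_competitor
#> 2     1        median close_competitor
#> 3     1           min close_competitor
#> 4     2           max close_competitor
#> 5     2        median close_competitor
#> 6     2           min close_competitor
```

Every phase × food-level curve of this low-food colony is classified as
close-competitor aggression — the generating regime. The curve behind the
phase-1 / poor-food label shows why (`mean` is the bootstrap-mean deviation
in pecks/day, `lo95`/`hi95` the percentile band):

```r
subset(res$curves, side == "attacker_older" & phase == "1" & biomass_level == "min")
#>              side phase biomass_level biomass_g delta_days    mean   lo95    hi95
#> 11 attacker_older     1           min      14.1         -4 -64.386 -67.08 -61.012
#> 12 attacker_older     1           min      14.1         -3 -38.681 -39.93 -37.410
#> 13 attacker_older     1           min      14.1         -2  -0.614  -1.91   0.491
#> 14 attacker_older     1           min      14.1         -1   9.066   7.38  10.100
#> 15 attacker_older     1           min      14.1          0  47.260  45.59  49.234
```

Siblings hatched 0–1 days apart are pecked far more than chance predicts
(+47 and +9 pecks/day), siblings 3–4 days younger far less (−39, −64): the
close-competitor signature. Allocation follows the same food gradient:

```r
alloc <- run_allocation_pipeline(ds, seed = 42)
alloc$fit
#> <allocation_fit> n=3760 bouts, observed shares S/M/J = 0.464/0.367/0.169
round(alloc$shares$vs_biomass[c(1, 25, 50),
      c("biomass_g", "share_S", "share_M", "share_J", "lo95_J", "hi95_J")], 3)
#>    biomass_g share_S share_M share_J lo95_J hi95_J
#> 1     14.122   0.399   0.476   0.125  0.072  0.220
#> 25    48.325   0.489   0.370   0.141  0.122  0.161
#> 50    83.953   0.335   0.253   0.412  0.335  0.497
```

The junior's predicted share of feeding bouts rises from 12.5% on the
poorest days to 41% on the richest (the `lo95`/`hi95` columns are
posterior-approximation bands per category), while the seniors' shares even
out —
the catch-up-growth opportunity that improving food conditions open for the
last-hatched nestling. Descriptive statistics mirror the calibrated colony
structure (phase-1 mean 201.9 pecks/brood-day; 67.7% of phase-1 pecks in the
senior→middle dyad):

```r
descriptive_stats(ds)$phase1$dyad_pct
#>    S>M    S>J    M>S    M>J    J>S    J>M
#> 67.685 15.823  9.740  6.116  0.215  0.421
```

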