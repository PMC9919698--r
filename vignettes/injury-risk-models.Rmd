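---
title: "Modelling non-contact injury risk from GPS training load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-contact injury risk from GPS training load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(injurycast)
```

## The problem and the unit of observation

Professional football squads monitor external load — distances, high-speed
running (HSR, 19.8–25.2 km/h), sprinting (>25.2 km/h), accelerometer-derived
player load, acceleration and deceleration counts — with wearable GPS/IMU
trackers. Non-contact lower-body injuries are believed to cluster where load
management fails: sudden spikes, prolonged troughs, and weeks whose match
demands are not prepared by the preceding training. The unit of observation
throughout this package is the **player-microcycle**: one training week
culminating in (at most) one match day, labelled 1 if a non-contact injury
occurred in that microcycle.

Each microcycle row splits into a training-week part (`mc_*`, sums over the
week's training sessions, match day excluded) and a match-day part (`md_*`).
Cumulative context (`TotalTrainingTime`, `TotalGameTime`, `Games`) counts
activity *before* the current microcycle and resets at the boundary between
the two competition rounds; every `mc_*`/`md_*` metric also carries lagged
copies `_-1`, `_-2`, `_-3` from the player's one-to-three preceding
microcycles in the same round. Because the lag suffixes contain a hyphen,
read feature CSVs with `read.csv(..., check.names = FALSE)`.

## Derived load ratios

The decision systems operate on ratio variables that compare a week against
its own history and against the match:

* `REG_<M>_R1_A = (mc_M + md_M) / (mc_M_-1 + md_M_-1)` — this week's total
  over last week's, for `M` in HSR, Sprint;
* `REG_<M>_R1_B`, `REG_<M>_R1_C` — the totals two and three weeks back over
  last week's total. The `B` variant is defined by interpolating the printed
  `A`/`C` pattern (two-back over one-back); it is referenced by the fuzzy
  rules but has no independent published definition;
* `REG_<M>_R2 = md_M / mc_M` — match demand relative to the training week;
* `REG_ACC_DEC` — match accelerations + decelerations over the training
  week's sum;
* `REG_ACWR_AC` — acute load: the week's total player load, match included;
  `REG_ACWR_HR` — chronic load: the mean of the acute load over the current
  and three preceding microcycles (a *coupled* ACWR: the current week is
  part of its own chronic window, which bounds the ratio at 4);
  `REG_ACWR = REG_ACWR_AC / REG_ACWR_HR`.

Two totality rules keep the ratios usable downstream. A ratio whose
denominator is exactly **zero** takes the neutral fallback value **1.1**
(inside the safe ACWR band); the published fallback is printed for the HSR
week-over-week ratio only, and is generalized here to every ratio on the
grounds that all are built on the same pattern. A ratio with **missing**
inputs (e.g. lags before the round start) stays `NA` and is left to
imputation — missingness is information about warm-up, not a zero
denominator. Rows where the player did not play carry `md_* = 0` rather
than `NA`, which keeps the `R2` ratios defined.

Player **motor profiles** (reference match values per metric) use the median
over the player's matches of at least 75 minutes — the threshold is
inclusive — with a same-position median fallback for players who never
qualify. Profiles feed the synthetic injury hazard (deceleration deficit);
they are exported but not consumed by the shipped rule bases, whose
published form references only the `REG_*` ratios.

## The three decision systems

### Banded expert rules

Six rules score one ratio each into {0, 3, 7, 10}. The ACWR rule is fully
published: 0 on [0.80, 1.30], 3 on [0.70, 0.80) and (1.30, 1.40], 7 on
[0.50, 0.70) and (1.40, 1.60], 10 beyond. The other five rules' true
thresholds were never published; the defaults reuse the same band geometry
on the analogous ratios, and every band is replaceable through a JSON
ruleset file (`write_ruleset()` / `load_ruleset()`), so a club's real rules
can be dropped in. The verdict is the **mean** of the available scores
(missing scores are excluded rather than imputed, to avoid biasing early
season rows toward either "safe" or "alarm"); a mean of at least **6.5**
(inclusive) flags the microcycle. `max` and `mode` aggregation remain
available behind a switch for comparison.

A consequence of the structural-analogy default worth knowing: the
match-to-week ratios (`R2`, `REG_ACC_DEC`) naturally sit below 0.5 in
ordinary weeks, where the ACWR geometry assigns the top score, so those two
rules contribute a constant alarm component on typical data. This is the
faithful default given what is published; replace those bands with
club-calibrated ones for operational use.

### Mamdani fuzzy rules

The fuzzy system blurs the sharp band edges. Each ratio becomes a
linguistic variable over [0, 3] with trapezoidal terms (`small`, `ok`,
`big`, ...), anchored around the crisp thresholds (0.5, 0.7, 0.8, 1.3,
1.4, 1.6) so that membership degrades linearly instead of switching at a
boundary. Thirty-four rules, including the five published ones verbatim,
map term combinations onto an output variable `load` on [0, 10]; inference
is canonical Mamdani: AND = min, OR = max, implication = clipping,
aggregation = pointwise max, defuzzification = centroid on a uniform grid
(step 0.01; checked in the tests against an independent fine-grid
trapezoidal-integration oracle to 1e-3). A crisp output strictly above
**0.6** flags the microcycle. The [0, 10] universe paired with a 0.6 cutoff
is taken as-is from the published design; it implies the benign consequent
term must concentrate its mass near zero (`very_small` is anchored at 0,
with centroid ≈ 0.42 when fully and solely activated), and it makes the
system flag whenever any alarm rule fires with non-trivial strength.

The 29 unpublished rules are generated from the published patterns
(jointly-small R1 triples → `very_small` load; out-of-band ACWR or acc/dec
ratio → `small`; big match-to-week ratios → `big`), extended with
persistence conjunctions (deviations on two adjacent lags) rather than
single-lag alarms, because single-ratio triggers fire on routine
week-to-week volume noise. Even so, under the synthetic conditions below
the fuzzy default trades precision for recall heavily — consistent with
the character this model class showed on the real data (it produced by far
the most false positives there). If no rule fires at all, the system
returns the output midpoint (5) with a warning — a deliberately
conspicuous "no knowledge" value rather than a silent 0. The whole base
serializes to an editable plain-text file (`write_knowledge_base()`) whose
rule section uses exactly the `IF (VAR IS term) AND ... THEN (load IS
term)` grammar.

### Gradient-boosting baseline

`train_and_tune()` fits an XGBoost classifier at the published
hyperparameters (500 trees, depth 7, eta 0.05, gamma 0.01, column
subsample 0.75, minimum child weight 0 — kept verbatim although unusual —
row subsample 0.5), evaluated by 5 × 10 repeated stratified
cross-validation with an optional grid search around that point. Two
preprocessing disciplines matter more than the booster:

* **Median imputation** statistics come from the training partition only
  (`impute_median(table, statistics_from = train)`), and inside CV from the
  training *fold* only.
* **SMOTE** rebalances the injury class by interpolating each synthetic
  point between a minority row and one of its k = 5 nearest minority
  neighbours (Euclidean on standardized features), up to exact class
  balance. By default SMOTE and imputation are fitted *inside* each
  training fold (leakage-free); `smote_nested = FALSE` reproduces the
  optimistic variant that rebalances once before CV, since the published
  description does not say which was used.

Three feature variants mirror the published comparison: everything plus
the expert-rule scores, everything without them, and the six rule scores
(plus their mean) alone. Gain-based importances are rescaled so the top
feature reads 100%.

## The synthetic squad generator

Real club data is private, so the generator stands in for it and defines
the conditions every test runs under: 36 outfield players (five positions),
two rounds of 20 and 11 microcycles, ~4.5% of player-microcycles missing
(call-ups, illness), 2–5 training sessions per week, a match scheduled
every week that each player plays with probability 0.8 (70% of played
matches are the full 90 minutes). Session metrics are lognormal around
position-specific medians — lognormal guarantees positivity and the right
skew of GPS loads — with a per-player ability multiplier; 10% of weeks are
spiked (×1.6–2.8) and 5% troughed (×0.25–0.45) to populate the risky ACWR
bands. With the default seed this yields 1064 player-microcycle rows
splitting 688/376 across the rounds, in line with the population the
package emulates (1064 events, 693/371). Per-session magnitudes are
plausible elite-football ranges; no public per-session table exists to
calibrate them against.

Injuries are drawn per row from a logistic hazard on exactly the signals
the expert rules monitor: `|log REG_ACWR|`, the HSR week-over-week excess
above 1.3 (capped at 3), and the deceleration deficit relative to the
player's motor profile, with configurable coefficients (defaults 3.0, 1.2,
1.0). The intercept defaults to "calibrate so the expected injury rate
equals `base_injury_rate`" (default 0.063, solved by `uniroot` on the
realized linear predictors); passing a numeric intercept disables the
calibration. This construction makes the mechanism *recoverable*: models
watching workload extremes beat chance by design, which is what the
recovery tests assert.

What the generator deliberately does **not** model: contact injuries,
internal load (heart rate, RPE), GPS measurement error, congested weeks
with two matches, post-injury layoffs (an injured player trains on next
week), and within-season drift in fitness. Passing tests therefore show
that the pipeline recovers a workload-driven mechanism under clean
conditions — not that these models reach any particular performance on
real club data, whose headline numbers are not reproducible from public
information.

```{r, eval = FALSE}
ds <- simulate_dataset(simulation_config())
f <- apply_ruleset(ds$features)
f <- apply_fuzzy(f)
parts <- split_train_test(f)           # round 1 trains, round 2 tests
fit <- train_and_tune(parts$train, ml_config())
compare_models(parts$test$Injury,
               list(rules = parts$test$rule_decision,
                    fuzzy = parts$test$fuzzy_decision,
                    ml = predict(fit, parts$test)))
```

## Numerical and design choices

* **Chronological split.** Training on round 1 and testing on round 2
  respects the two-round data collection; a random split would leak
  within-player temporal structure through the lags.
* **Defuzzification grid.** Step 0.01 over [0, 10] (1001 points); the
  centroid of piecewise-linear aggregates converges quadratically in the
  step, and the test suite bounds the error against a 1e-4-step
  trapezoidal oracle at 1e-3.
* **Metric conventions.** Precision, recall and F1 are reported as `NA`
  (undefined) when their denominator is zero, never silently 0; F1 is 0
  exactly when there are no true positives but both denominators are
  defined. Metrics target the injury class.
* **Determinism.** One seed fans out to every stochastic stage by fixed
  offsets (`run_pipeline()` records seed, config hash and file checksums
  in a manifest); identical configuration and seed reproduce every file
  byte for byte. The booster runs single-threaded by default for the same
  reason.
* **Problem sizes in the tests.** Module tests use squads of 8–25 players
  over 12–20 microcycles; the mechanism-recovery test uses the full
  default squad (one ~1064-row dataset, one 5 × 10 CV run at the default
  grid point). These sizes were chosen as the smallest at which the
  asserted effects are stable across seeds.

## Known limitations

The five unpublished expert rules and all fuzzy membership parameters are
structural analogies, not recovered truth; both are config files precisely
so that a club can substitute its own. The published confusion counts for
the rule-based model (21 true positives, 1 false negative against 31 test
injuries with recall 58%) are mutually inconsistent, so no code path
attempts to match them; the package reports metrics from its own confusion
matrices. The generator's injury hazard is memoryless across weeks and
players; real injury processes are neither.
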