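---
title: "Estimating crisis-year excess mortality with enveloping intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating crisis-year excess mortality with enveloping intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envexcess)
```

## The problem

A short, intense crisis — a six-week war, a pandemic wave — leaves its
trace in annual vital-registration tables as a departure of the observed
death count from what the pre-crisis years would have predicted. With
only a handful of reference years per stratum (country × sex × age
group), often small counts, and genuine uncertainty about the right
baseline model, the estimation problem is less about a clever estimator
than about honest uncertainty: a predictive interval for a *single future
count*, robust to the choice of baseline.

`envexcess` implements that workflow: three baseline forecasts per
stratum, a conservative combination, observed-minus-expected excess with
bounds, and aggregation over age ranges chosen to separate a conflict
signal (concentrated in fighting-age men) from a concurrent pandemic
signal (concentrated at old ages).

## The three baselines

All three models treat deaths as over-dispersed Poisson counts:
Var(d) = φ·E(d) with φ ≥ 1.

**OPM (over-dispersed Poisson mean).** The point forecast is the
reference-window mean. For a log-link intercept-only quasi-Poisson model
this is also the MLE, and the variance of the fitted log-mean has the
closed form φ/(n·μ̂), which the implementation uses directly rather than
through `glm`.

**OPT (over-dispersed Poisson trend).** A year trend captures secular
change (improving traffic safety, shifting age composition within
groups) that the mean would smear into the forecast. The default link is
log — a log-linear trend keeps forecasts positive and treats relative
change as constant, which is how mortality trends are usually modelled —
with an identity-link (straight-line) variant exposed as a sensitivity
option (`opt_link = "identity"`). Coefficients are fitted by Poisson
`glm`; the dispersion multiplies the squared standard errors afterwards,
which avoids re-scaling issues when the Pearson dispersion of a
near-perfect fit drops below 1 (φ is floored at 1 throughout).

**LC (count Lee-Carter).** The classical decomposition
log d(i,t) ≈ α_i + β_i κ_t is fitted to the country's *entire*
age–sex × year matrix: α is the row mean of the log counts, (β, κ) the
first singular pair of the row-centred matrix, normalised to Σβ = 1,
Σκ = 0. Pooling the matrix lets a stratum with five noisy points borrow
the common time signal κ. κ is forecast by a random walk with drift:
drift = mean first difference, innovation variance = sample variance of
first differences. There is no second-stage refit of κ against total
deaths — with a five-year window it would be fitting noise. Applying a
log decomposition to counts (not rates) assumes stable population sizes
over the window; the rates variant below drops that assumption.

### Predictive intervals

Intervals are built by parametric simulation, identical in structure for
all three models:

1. draw the linear predictor η from η̂ + se(η̂)·t(df), with df the
   residual degrees of freedom (n−1 for OPM, n−2 for OPT, one fewer than
   the number of κ increments for LC);
2. draw a count from a negative binomial with mean exp(η) and variance
   φ·exp(η) (exact Poisson at φ = 1);
3. report the empirical 2.5/97.5 percentiles of `pi_draws` draws
   (default 100,000; continuous type-8 quantiles; the lower bound is
   clipped at 0).

Simulation rather than a normal approximation is essential at small
counts, where the predictive distribution is markedly skewed and a
Wald-type interval would go negative. The t draw (rather than the
asymptotic normal) is the same small-sample correction `lm` prediction
intervals use: with four or five reference years the plug-in φ is very
noisy, and the normal draw undercovers. The simulation-based coverage
study below is the check that this construction earns its 95% label.

For LC, step 1 draws κ(T) from its random-walk forecast distribution —
variance h·σ² for h forecast steps plus h²·σ²/Σ(Δt) for the estimated
drift — and all strata share one φ estimated from the matrix-wide
Pearson statistic. When a reference year is excluded (the robustness run
below), κ increments are weighted by their year spacing, which reduces
to the standard estimates on contiguous years.

### The envelope

The final expected estimate per stratum is the *enveloping interval* of
the three models: highest point, lowest lower bound, highest upper
bound (`argmax_model` records the source of the point; ties break in the
fixed order OPM < OPT < LC for determinism). Excess is observed minus
the envelope point, with bounds from subtracting the envelope bounds.
Because the envelope interval contains each model's interval, its
coverage can only match or exceed the best single model's — that
containment is deterministic, not statistical.

The flip side is a deliberate bias: taking the *highest* expected point
makes the excess point the *lowest* of the three, so under a true null
the envelope excess sits at or slightly below zero rather than centred
on it. This is the design's false-positive protection, and it is why the
specificity checks in the test suite assert "no positive signal beyond
Monte-Carlo error and a small conservatism offset relative to the
injected shock" rather than exact centring at zero.

### Aggregation

Age-range aggregation keeps whole age groups only (no pro-rating) and
sums excess points *and both bounds* across strata. Summing bounds
ignores cross-stratum independence — treating the strata as
perfectly dependent — and is therefore conservative too; it is also the
arithmetic that makes a summary table's total row exactly the sum of its
country rows. Rounding to whole deaths happens only when the formatted
report is emitted; all internal arithmetic keeps full precision, so
grand totals computed from unrounded internals can differ by ±1 from
the sum of *rounded* sub-totals a reader would do by hand.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `reference_years` | 2015–2019 | pre-crisis window (years) |
| `target_year` | 2020 | forecast year |
| `exclude_years` | none | years dropped from the window (e.g. 2016) |
| `level` | 0.95 | predictive-interval level |
| `pi_draws` | 100,000 | simulation draws per interval |
| `seed` | fixed | seed for all interval simulations |
| `opt_link` | `"log"` | OPT trend link |
| `zero_offset` | 0.5 | replacement for zero cells before LC logs |
| `age_range` | 15–49 | reporting aggregation range (years of age) |

The default age scheme has 16 groups — 0, 1–4, then 5-year groups up to
65–69 and a terminal 70+ — keeping the separate infant group that the
J-shaped schedule needs; the scheme is a configurable value, so 75+ or
85+ terminal variants are one `age_scheme()` call away. The 15–49
reporting default spans seven whole 5-year groups: old enough to exclude
childhood mortality, young enough to exclude the ages where a concurrent
pandemic dominates.

The rates variant (`mode = "rates"`) refits OPM/OPT with a log-exposure
offset and LC on death rates, returning results on the deaths scale; it
requires a positive exposure (person-years) table covering the reference
*and* target years, and exists because count-scale forecasts silently
assume stable exposure (migration, displacement).

## The synthetic registry

`scenario_config()` defines a deterministic expected surface —
log-linear in a J-shaped age schedule, a male/female log-ratio, and a
secular trend — on which counts are drawn independently per cell from a
negative binomial with variance `dispersion` × mean. Crisis shocks
modify the surface only in their year and strata: multiplicative shocks
scale expectations (a pandemic-style rate ratio), additive shocks add a
fixed total of expected deaths apportioned proportionally to baseline
(a conflict-style death toll). `karabakh_preset()` combines both: a
1,000-death additive shock in males 15–49 and a 1.25× shock at 60+ in
2020, on a registry of roughly 23,000 deaths per year; `artsakh_preset()`
scales everything down to tens of deaths per year so that zero-count
paths are exercised.

Default generator values were fixed once, on demographic plausibility:
dispersion 1.3 (mild extra-Poisson noise typical of annual registration
counts), male/female ratio 1.4, trend −1% per year (slow mortality
decline), and an age schedule descending from 150 infant deaths to a
school-age minimum and rising to a dominant open-ended group.

What the generator deliberately does *not* emulate: shared year effects
beyond the smooth trend (a flu season lifting all strata at once),
migration or population renewal, cause-of-death structure, and late or
displaced registration. Cells are independent given the surface, which
matches the estimators' working assumptions — so the calibration results
below validate the *implementation* under its own model, not the models
against real registries, where correlated year shocks would widen true
uncertainty beyond the nominal level.

## Validation harnesses and problem sizes

`calibration_study()` repeatedly samples registries, fits everything on
the reference years, and reports (a) per-model and envelope coverage of
the held-out target-year count in non-shocked strata, (b) mean bias of
the expected points against the no-shock surface, and (c) aggregated
excess against the true injected shock. The package's own test suite
runs it at 2,000 replicates on a compact 8-stratum, zero-trend scenario
(a configuration that is simultaneously inside all three model classes,
so each model is correctly specified at once) with 2,000 draws per
interval, and at 200 replicates on the full 32-stratum conflict preset
with 1,000 draws — sizes chosen to pin coverage and bias to within
about a percentage point while keeping a laptop run in minutes.
Shock-recovery tolerance is 15% relative bias, documented slack for the
envelope's downward conservatism plus Monte-Carlo error.

`robustness_suite()` re-runs a configuration with a reference year
dropped (default 2016) and on death rates, reporting absolute and
relative changes in the aggregate excess — the two standard checks that
a registry anomaly or exposure drift is not driving the headline number.

## Numerical choices and degenerate inputs

- φ is Pearson X²/df, floored at 1; per-stratum for OPM/OPT, shared for
  LC. All-zero series return φ = 1 and a degenerate [0, 0] interval by
  convention.
- Zero cells enter LC as log(`zero_offset`) with a warning;
  `zero_offset = NULL` makes zeros a hard error instead.
- Simulated means are capped at 10⁸ before count draws: near-degenerate
  fits on tiny series can push exp(η) past the integer-RNG ceiling,
  where `rpois`/`rnbinom` return `NA`. On real registry scales the cap
  is orders of magnitude out of reach; on pathological inputs it turns
  an `NA` crash into a finite (huge) upper bound, which is the honest
  summary of such a fit.
- SVD sign ambiguity is resolved by making Σβ positive before
  normalising; a leading singular vector summing to ~0 (no common age
  pattern) is a hard error rather than a silently unstable fit.
- Envelope ties and row ordering are fully deterministic, and every
  stochastic step takes an explicit seed, so identical configurations
  produce byte-identical output files.

## Limitations

Total excess cannot be decomposed into direct (combat) and indirect
(service-disruption) mortality from registration counts alone; age-sex
selectivity is the only lever, and it is an argument, not a proof. The
envelope's conservatism is asymmetric — it guards against false
positives at the cost of a downward-biased excess point — and summed
bounds overstate aggregate uncertainty when strata are close to
independent. Five reference years identify a trend and a drift only
weakly; the OPT and LC intervals are honest about that (they widen), but
no interval construction can recover information that short a window
does not contain.
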