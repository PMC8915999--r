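---
title: "Estimating lifespan measures from crowdsourced genealogies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lifespan measures from crowdsourced genealogies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genlex)
```

## The problem

Crowdsourced online genealogies hold millions of individual life courses
spanning centuries — a tempting source for historical demography, where
official life tables rarely reach back before the mid-19th century.  But
a genealogy is not a census.  Which lives end up recorded depends on who
was visible to history and to the genealogists: coverage of the total
population is typically poor in early periods, and socially prominent
people (here proxied by *scholars* — members of universities and
academies of sciences, an elite with a documented mortality advantage)
are heavily overrepresented.  Lifespan statistics computed naively from
such data can therefore resemble an elite, not the population.

`genlex` implements the full estimation chain for two headline measures
of adult male mortality —

* **e30**, remaining life expectancy at age 30, and
* the **Gini coefficient of remaining lifespan at 30**, a measure of
  lifespan inequality —

together with the diagnostics needed to judge whether a genealogy-based
estimate is representative: yearly *coverage* of the population,
record-linkage of an elite roster into the genealogy, per-period elite
*oversampling* factors, and the correlation between those drivers and
how closely the genealogy's e30 tracks the elite's.

Because real genealogy exports cannot be redistributed, the package
ships a synthetic-data generator with known Gompertz–Makeham ground
truth that emulates the relevant data pathologies.  Every estimator in
the package is validated against that ground truth.

## The estimation chain

### Cleaning

`clean_records()` applies, in a fixed auditable order: a territory rule
(a record belongs to a territory if it was born *and/or* died there — a
declarative predicate over normalized place strings, not a GIS
operation), a sex filter, duplicate removal, removal of death ages above
100 years (transcription errors), removal of deaths after 1910 (the
genealogy's reliable horizon), and optionally removal of records without
exact dates.  Every stage's removals are counted in a `cleaning_report`
whose arithmetic must reconcile exactly; cleaning is idempotent and
order-invariant.

The duplicate key is a design decision: identical birth date, death
date, and *normalized* birth place (case-folded, accents transliterated,
punctuation stripped), keeping the lexicographically smallest person id.
This is deterministic and conservative — near-copies that differ only in
spelling collapse, genuinely different people sharing a date do not.

### Lexis tabulation and left truncation

`tabulate_lexis()` converts lifelines into death counts and person-year
exposures on half-open age × period cells.  Year-precision dates are
imputed at mid-year (+0.5), which is unbiased under uniform within-year
timing.  Exposure is exact interval intersection: time lived inside
(age band) ∩ (calendar period) ∩ [birth + entry age, death).

Scholars enter observation at their first academic appointment, often
after age 30, so their person-years before appointment must not be
counted: that is the left-truncated "wLT" variant
(`use_entry_age = TRUE`).  The "woLT" variant ignores entry ages; it is
less accurate — it counts pre-entry person-years during which no death
could have been observed, so it understates adult mortality and
overstates e30 — but it is the variant comparable to the genealogy
estimate, which cannot account for truncation.  An optional
right-censoring mode lets deathless records contribute exposure up to
the horizon year (a robustness variant; the main analysis uses deaths
only).

### P-spline smoothing

Death rates on a fine grid are noisy; `fit_psplines_2d()` smooths the
log death-rate surface over age and calendar time with two-dimensional
P-splines under a Poisson model:

$$D_{ij} \sim \mathrm{Poisson}\!\big(E_{ij}\, e^{\eta_{ij}}\big),
\qquad \eta = (B_p \otimes B_a)\,\theta,$$

with equally spaced B-spline bases (cubic by default; knots every 5
years of age and 10 calendar years) and second-order difference
penalties $\lambda_a$, $\lambda_p$ on the coefficients in each
direction.  The penalized likelihood is maximized by iteratively
reweighted least squares with step-halving, so it is non-decreasing by
construction.  Numerical safeguards: a ridge floor of 1e-6 on the
normal equations, initialization at log((deaths + 0.5)/(exposure + 1)),
convergence when the largest coefficient change falls below 1e-6 (cap
200 iterations).  Cells with zero exposure get zero weight; their
fitted values are pure penalty interpolation.

Smoothing weights can be selected by grid search on
BIC = deviance + log(#positive-exposure cells) × effective dimension
(`select_lambdas()`), with ties broken toward smoother fits.  One
property worth knowing: the null space of the 2D second-order penalty is
the *bilinear* family $a + b\,\mathrm{age} + c\,\mathrm{period} +
d\,\mathrm{age}\cdot\mathrm{period}$ — affine in each coordinate
separately — so the infinite-smoothing limit retains an age × period
interaction.  The tests check this limit against the bilinear surface.

### Abridged life tables, e30, and the Gini coefficient

`mx_to_lifetable()` builds standard abridged period life tables on
5-year age groups with an open 80+ interval: $q_x = n m_x / (1 + (n -
a_x) m_x)$ capped at 1, $a_x = n/2$ for interior groups (the main text
sources give no $a_x$ rule; this is the standard convention), terminal
group $q = 1$, $L = l/m$, $a = 1/m$.  Then e30 = T(30)/l(30).

The Gini coefficient of remaining lifespan is the definitional
$G = E|X_1 - X_2| / (2\,E X)$ for two independent remaining lifespans
under the life table's discrete death-age distribution (death in group
$i$ with probability $d_i / l_{30}$ at remaining age $x_i - 30 + a_i$),
computed by the exact double sum over groups.  Computing it on the
discrete group-level distribution — rather than a continuous
interpolation — makes it fully determined by the table and exactly
reproducible; the tests validate it against a Monte Carlo sampling
oracle to within 0.002.  A discretization of this kind slightly
understates the continuous-lifespan Gini, which is why benchmark
comparisons should use the same table layout on both sides.

### Uncertainty

Following the binomial death-count model, `resample_lifetables()`
reconstructs per-group trial counts $N_x = \max(\mathrm{round}(D_x /
\hat q_x), D_x)$ — which reproduces the point estimate in expectation —
draws $D^*_x \sim \mathrm{Binomial}(N_x, \hat q_x)$, rebuilds the life
table per replicate (1,000 replicates by default), and reports the
2.5th/97.5th percentile interval and replicate mean for both e30 and
Gini.  The terminal group has $q = 1$ identically, so replicates keep
the point estimate's terminal rate.  A calibration experiment in the
test suite (500 synthetic cohorts of 2,000 lifespans, 200 replicates
each — sizes chosen as a realistic territory-period death count at desk
scale) finds empirical 95% coverage of about 0.95.

Whether resampling should happen before or after smoothing is
underdetermined; the default here resamples the grouped counts and
rebuilds the table directly, which is the fast variant appropriate when
the table feeding the interval is itself the object of interest.

### Representativeness diagnostics

* `interpolate_population()` fills sparse historical population-size
  anchors assuming exponential growth between anchors (log-linear
  interpolation); extrapolation is refused.
* `coverage_series()` counts sample records alive at each mid-year and
  divides by population size.  Coverage above 1 is flagged, not dropped.
* `match_scholars()` links a scholar roster into the genealogy by
  blocking on birth and death year (± a tolerance), requiring month
  agreement where both sides know it, and requiring normalized
  edit-distance place similarity ≥ 0.85 for birth or death place.
  Conflicts are resolved by highest score with deterministic
  tie-breaks; the result is one-to-at-most-one in both directions.
  Name-based matching is deliberately out of scope.
* `oversampling_series()` is (matched scholars alive / sample alive) ÷
  (scholars in population / population size) per period.
* `resemblance_correlation()` correlates a driver series (coverage or
  oversampling) with *resemblance*, defined as the negative absolute
  gap between the sample's e30 and the elite's woLT e30.  The
  resemblance functional is a package design decision — "the degree to
  which the sample resembles the elite" admits many formalizations — so
  it is pluggable; the negative-absolute-difference default makes the
  expected correlation signs interpretable (negative with coverage,
  positive with oversampling).  Pearson correlation is used.

## The synthetic world

`generate_population()` draws exact-dated male lifelines with
Gompertz–Makeham lifespans (hazard $r(c + a\tau^{t}e^{bx})$) by
inverse-CDF bisection to 1e-8 years, with an elite stratum whose hazard
is multiplied by a ratio < 1.  `sample_genealogy()` then applies the
ascertainment model: inclusion probability affine in birth year
(anchored at the midpoint of the birth-year range, so the base rate
stays interpretable), multiplied for elites, clamped to [0, 1]; plus
near-duplicate profiles (same vital dates, place spelling perturbed only
by case/accents/punctuation so the dedup key still identifies them),
death ages inflated past 100, and dates coarsened to bare years.

`generate_scholar_roster()` draws an appointment age for each elite
independently of their lifespan and keeps only those who survive to it
(`selection = "thin"`).  This detail matters: *redrawing* an infeasible
appointment age instead (`selection = "redraw"`, kept for sensitivity
analysis) makes entry age dependent on lifespan — every short-lived
elite still enters the roster, just with an earlier entry — which is an
informative-truncation defect that biases the wLT estimator low by more
than a year at study scale.  Thinning reproduces exactly the
independent left-truncation mechanism the wLT estimator assumes, and
the tests confirm wLT then recovers the true elite e30 to within 0.3
years.

What the generator does *not* emulate: pedigree/network structure,
name vocabularies, female mortality, non-random missingness driven by
lineage extinction, or genealogist behavior.  Passing tests therefore
demonstrate that the estimators are correct under the stated sampling
model, not that any particular real genealogy satisfies that model.
The true mortality regimes behind historical data are unknown; the
synthetic regimes are parameterized, not calibrated to any published
series.

## Study designs used in the validation suite

Problem sizes were chosen once, as realistic desk-scale analogues of
territory-level genealogy samples:

* Oracle-equivalence checks: 50,000 lifespans; Gini sampling oracle at
  10^6 draws.
* Smoothing recovery: a drifting Gompertz surface with ~50,000 deaths
  on a 60 × 40 one-year grid; log-rate RMSE is assessed on cells with
  more than 100 person-years.
* CI calibration: 500 cohorts × 200 replicates as above.
* Truncation: 30,000 scholars with appointment ages uniform on
  [30, 45].
* Representativeness recovery: 100,000 persons, inclusion 0.10, elite
  multiplier 5, elite fraction 0.002 (so the analytic expectations of
  coverage and oversampling stay within a fraction of a standard error
  of the nominal 0.10 and 5).
* Bias phenomenon: 20 replicates of a two-stratum world (40,000
  persons, elite fraction 0.05, elite hazard ratio 0.6, elite
  visibility multiplier 30, inclusion rising from ~0.02 to ~0.4 across
  birth years).  In each replicate the per-period sample e30 starts
  near the elite series and migrates toward the general value as
  coverage rises; the coverage–resemblance correlation is negative and
  the oversampling–resemblance correlation positive in at least 18 of
  20 replicates.

## Degenerate inputs and edge policies

* Point-mass lifespans: the life-table Gini is exactly 0 and all draws
  equal the point mass — used as analytic limit checks.
* Zero-exposure age groups abort life-table construction (and binomial
  resampling) with the group named, never silently.
* `q_x > 1` after the rate conversion is capped at 1 with a warning.
* Records with both places missing fail the territory rule and are
  excluded (logged in the report).
* Unparseable dates and death-before-birth rows go to a rejects table
  with reasons, never silently dropped.
* "After 1910" means death year strictly greater than 1910; deaths in
  1910 are kept.

## Known limitations

* The pipeline produces period life tables only (no cohort
  parallelograms) and no single-year tables.
* The abridged Gini is a grouped-data quantity; comparisons against
  continuous benchmarks carry a small systematic discretization gap.
* The matcher is year/month/place-based only; in data with heavy place
  misspelling beyond accent/case noise its recall would degrade.
* No extrapolation of the smoothed surface beyond the data's age/period
  hull, and no mortality forecasting.
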