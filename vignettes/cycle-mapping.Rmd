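---
title: "Mapping cycles from daily urinary hormones: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cycles from daily urinary hormones: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cyclemap)
```

## The measurement model

A subject tests first-morning urine on directed days across one cycle.
Sandwich-format lateral-flow lines (LH, FSH) darken with analyte
concentration; competitive-format lines (E1G, PdG) fade. A reader converts
line intensity to concentration through per-hormone standard curves, so the
package works in concentration units throughout: E1G in ng/mL, LH and FSH
in mIU/mL, PdG in µg/mL. Cycle day 1 is the first day of red menstrual
bleeding; untested days are absent, and a hormone not measured on a tested
day is `NA` — the detectors only ever reason over measured values and never
impute.

The physiology the rules encode: rising E1G marks a recruiting follicle and
opens the window of possible conception (sperm survival); the LH surge
marks peak fertility and normally precedes ovulation; PdG is low through
the follicular phase and rises only after ovulation, so a post-surge PdG
rise *confirms* ovulation; and sustained PdG across days 7–10 after the
peak (the implantation window) distinguishes a sufficient luteal phase from
ovulatory dysfunction. Early-cycle FSH screens ovarian reserve, a separate
axis from ovulatory function.

## Decision thresholds

All cut-offs live in one `cycle_thresholds()` object so that every decision
the engine takes is auditable and overridable (also from a JSON config via
`read_thresholds()`):

| parameter | default | units | comparison | role |
|---|---|---|---|---|
| `lh_surge` | 25 | mIU/mL | strict `>` | surge / peak fertility |
| `e1g_abs` | 175 | ng/mL | inclusive `>=` | absolute part of the rise rule |
| `e1g_baseline_ratio` | 1.5 | — | inclusive `>=` | relative part, vs the day-5 baseline |
| `pdg_confirm` | 2.5 | µg/mL | inclusive `>=` | ovulation confirmation |
| `pdg_sustain` | 5 | µg/mL | inclusive `>=` | sustained-day counting |
| `fsh_elevated` | 10 | mIU/mL | strict `>` | ovarian-reserve flag |

The strict/inclusive split follows the validated wording of each rule ("over
25", "as low as 2.5", "over 10"); where usage alternates ("above" vs
"reaching" 5 µg/mL) we fixed the inclusive reading once and documented it.
The E1G rise criterion deserves a note: a "significant rise" has no single
published definition, so this package uses the conjunction
`E1G >= max(e1g_abs, e1g_baseline_ratio × baseline)` with the baseline taken
from the earliest measured day (the directed day-5 test). The absolute arm
is the meaningful physiological concentration used for assay sensitivity;
the relative arm guards against subjects whose baseline already sits near
it. Both arms are configurable, so other operationalisations can be swept.

Derived quantities: the fertile window runs from the E1G-rise day to the
PdG-rise day as a day-index difference (same-day E1G rise and LH surge with
a next-day PdG rise gives 0 + 1 = 1 fertile day; a 7-day E1G→LH gap with a
4-day LH→PdG gap gives 11). When no E1G rise exists but ovulation is
confirmed, the window opens at the LH peak — forced by the observed
pattern of a 1-day window in a cycle without any E1G rise. When multiple LH
surge episodes occur, the peak is the first day of the *first* episode and
the implantation window is anchored there; the episode count is surfaced so
callers can filter the (genuinely ambiguous) multi-surge cycles themselves.
No upper limit is imposed on the LH→PdG gap, and no fixed observation cap
declares a cycle anovulatory: the call is "no PdG rise by the end of the
provided series".

## Classification and the Ovulation Score

Over the four implantation-window offsets (peak + 7…10), with missing days
never imputed:

* anovulatory ⇔ no PdG rise anywhere;
* successful ovulation: ≥ 3 tested days with PdG ≥ 5 µg/mL;
* ovulatory dysfunction: ≥ 2 tested days below 5 µg/mL;
* indeterminate: < 3 of the 4 offsets tested, or the one undecidable cell
  (exactly 3 tested, 2 high / 1 low) where neither rule fires.

The Ovulation Score endpoints are fixed by the definitions (100 = all four
days sustained, 10 = none), but the 20–90 interior is not published
anywhere, so the package's banding is deliberately simple and isolated in
one function: base 30/50/70 for 1/2/3 sustained days, +10 when the mean
implantation-window PdG is ≥ 5 µg/mL, −10 when it is below 2.5 µg/mL,
clamped to [20, 90]. A cycle with no confirmed ovulation is reported
without a score rather than as a 10 — an anovulatory cycle is "not
confirmed", not "confirmed with poor luteal output".

The testing schedule helper predicts ovulation as average cycle length
minus 14 days. Fixed day-14 ovulation is exactly the assumption quantitative
monitoring replaces, but a *pre-cycle* prediction is still needed to direct
when daily testing starts, and length − 14 (a default-luteal-phase
convention) is the standard choice; actual event timing then comes from the
hormones, not the prediction.

## Calibration and QC statistics

Sandwich curves are fitted by ordinary least squares on intensity vs
concentration; competitive curves by OLS on log intensity, i.e.
`log I = log A − k·c`. A log-linear fit (rather than iterative nonlinear
least squares) was chosen because the QC protocol reports a single
correlation coefficient per best-fit line, and that quantity is only
well-defined on the linearised scale. `r_value` is the signed Pearson
correlation on the fitted scale — negative for competitive lines — and the
reproducibility gate applies to |r|: at least 90 % of per-lot ×
technician × day fits must exceed 0.9, alongside every per-day and pooled
replicate %CV below 10 (sample SD, n−1, throughout; %CV is scale-invariant
so the gate is unit-free). Acceptance bounds for sensitivity/specificity
are mean ± 3 SD of the validation-lot readings with inclusive comparisons
(a strip exactly on the bound passes), and a lot passes when ≥ 90 % of
strips satisfy the bound. Zero-concentration points are retained in
exponential fits whenever their intensity is positive; non-positive
intensities have no log transform and are rejected. Curve inversion clamps
at zero concentration, and an intensity of exactly zero under the
exponential form has no inverse. The specific published acceptance-range
values cannot be regenerated without the raw bench readings, so the tests
exercise the machinery on constructed and simulated panels instead.

## What the simulator emulates — and what it does not

`simulate_cycle()` builds the directed testing calendar (day-5 baseline,
FSH on days 5/7/9, daily multi-hormone testing from 5 days before predicted
ovulation until the PdG rise, plus the four implantation-window days) and
fills it with piecewise phase templates: a follicular E1G ramp capped at
78 % of the rise threshold until the planted rise day, a 2-day LH pulse at
45 mIU/mL on a 5 mIU/mL base, and a saturating PdG ascent from a 0.81 µg/mL
pre-ovulatory base through 3.3 µg/mL on the planted confirmation day toward
the phenotype's plateau (8 µg/mL for normal cycles, 4 µg/mL for
luteal-deficient ones). Noise is multiplicative log-normal at a configurable
assay CV (default 5 %, consistent with how strip precision is
characterised), mean-preserving. One deliberate deviation from the directed
schedule: when the planted E1G rise precedes "predicted ovulation − 5",
testing is extended back to the rise day so that planted events remain
observable — with E1G→LH gaps up to 7 days the nominal start would
otherwise truncate the longest windows. The template margins (0.78× below /
1.25× above the E1G threshold, 45 vs 25 for LH, 3.3 vs 2.5 and 0.81 vs 2.5
for PdG) are ≥ 4.5 noise SDs from every decision boundary at 5 % CV, which
is what makes the ≥ 99 % planted-event recovery property hold.

`simulate_cohort()` reproduces the pilot-study cohort structure: 38
ovulatory cycles (22 normal, 16 luteal-deficient) plus 2 anovulatory ones
(the first with three LH surge episodes, the PCOS-like case), gap lengths
drawn from truncated Poisson distributions on {0…7} moment-matched to means
of 2.68 (E1G→LH) and 2.64 (LH→PdG) days, and elevated FSH assigned with
probability 0.43. Only means, ranges and CIs of the gaps are published, so
a discretised single-parameter family matched to the mean is the least
presumptuous choice; the two gaps are drawn independently because their
joint distribution is unreported. Since every ovulatory phenotype in the
preset has an E1G rise, the expected pipeline fertile window is exactly
2.68 + 2.64 = 5.32 days. Seeding contract: one root seed draws one substream
seed per cycle up front, and each cycle's gaps, FSH status and noise come
from its own substream, so enlarging a cohort never reshuffles earlier
cycles.

What the simulator does *not* emulate: cycle-length variability and its
correlation with event timing, luteinised unruptured follicles and other
LH/PdG dissociations beyond the modelled phenotypes, assay nonlinearity at
range edges, user error (missed or mistimed tests beyond the schedule
gaps), and any joint gap structure. Passing tests therefore demonstrate
that the rule engine is correct *given* its thresholds and testing
schedule, not that those thresholds are clinically optimal — threshold
validity rests on the underlying clinical evidence, not on these
simulations.

## Cohort statistics

`summarize_cohort()` reports n, mean, range and a t-based 95 % CI
(mean ± t₀.₉₇₅,ₙ₋₁ · s/√n, sample SD) per parameter over ovulatory cycles
only; anovulatory cycles are tallied but excluded from day-parameter
statistics, mirroring how the study cohort was analysed. Group comparisons
default to Welch's unequal-variance t-test — the published group p-values
name no test, and the compared groups are unequal in size (22 vs 16), which
argues against the equal-variance form — with a Monte-Carlo permutation
test available as a distribution-free cross-check. Degenerate case: two
zero-variance groups compare as p = 1 when means agree, p = 0 otherwise.
No multiplicity correction is applied (none was in the source analysis).
With windows drawn from the preset's discrete gap distributions, the
t-interval's empirical coverage at n = 38 sits in the 93–97 % band over
1,000 simulated cohorts — checked in the test suite.

## Numerical and interface choices

* Threshold comparisons use exact floating-point semantics; the recovery
  tests probe them on a 0.01-step grid whose critical points (2.5, 5, 10,
  25) are exactly representable doubles.
* Curve fitting delegates to `stats::lm`/`cor`; CIs and Welch tests to
  `stats::t.test`. The package's own contribution is the rule engine, the
  score, the simulator and the QC gating logic.
* CSV dialects: cycles as
  `subject_id,cycle_day,e1g_ng_ml,lh_miu_ml,pdg_ug_ml,fsh_miu_ml` (empty
  cell = not measured; malformed rows collected into an error report with
  line numbers, never silently dropped), QC panels as
  `lot,technician,day,hormone,concentration,intensity`. JSON outputs are
  schema-versioned. Reports render deterministically to JSON, Markdown or
  HTML; the interpretation bands in the report are this package's own.
* Problem sizes used by the test suite and the acceptance script: cohorts
  of 38–40 cycles at study scale, 5,000 cycles for convergence checks,
  300 cycles for the recovery property, 1,000 replicate cohorts for CI
  coverage.

## Known limitations

The E1G-rise criterion and the interior Ovulation Score bands are this
package's documented conventions, not published definitions — both are
parameterised and isolated so alternatives can be evaluated. The
implantation window is always anchored to the first surge episode, which is
one defensible reading of an ambiguous multi-surge situation. Published
cohort-specific results (the exact 38/40 split, 22 successful cycles, 43 %
elevated FSH, the printed CIs and p-values) depend on participant-level
data that is not public; the package reproduces the machinery that computes
such tables, and its simulator preset reproduces the cohort's *configured*
structure, not those specific numbers.
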