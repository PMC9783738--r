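# cyclemap

Quantitative menstrual-cycle mapping from daily urinary hormone
measurements.

At-home lateral-flow test systems now quantify four urinary hormones across
a cycle: follicle-stimulating hormone (FSH) early in the cycle,
estrone-3-glucuronide (E1G, the urinary metabolite of estradiol),
luteinizing hormone (LH), and pregnanediol-3-glucuronide (PdG, the urinary
metabolite of progesterone). Read together, these map the whole cycle: the
E1G rise opens the fertile window, the LH surge marks peak fertility, a
post-surge PdG rise confirms that ovulation occurred, and sustained PdG
through the implantation window separates a fully functional luteal phase
from ovulatory dysfunction — the leading cause of female-factor
infertility. `cyclemap` implements that rule engine for analysts and
clinicians working with such data, plus everything needed to validate it:
assay calibration/QC statistics, a synthetic cycle simulator, and
cohort-level summaries.

## The rules

For a daily series (cycle day 1 = first day of menses; untested days simply
absent), with default thresholds:

* **E1G rise** — first day with
  `E1G >= max(175 ng/mL, 1.5 x baseline)`, the baseline being the directed
  day-5 test. Opens the fertile window.
* **LH surge** — maximal runs of consecutive measured days with
  `LH > 25 mIU/mL` (strict). Peak fertility = first day of the first
  episode; multiple episodes are reported (a PCOS-type pattern).
* **PdG rise** — first day at/after the peak with `PdG >= 2.5 µg/mL`
  (inclusive). Confirms ovulation and closes the fertile window; with no
  E1G rise the window opens at the peak instead.
* **Fertile window** — `pdg_rise_day − open_day`, decomposed as
  (E1G→LH gap) + (LH→PdG gap); day-index differences, so same-day events
  give gap 0.
* **Ovulatory function** over the implantation window (days 7–10
  post-peak): ≥3 of the 4 tested days with `PdG >= 5 µg/mL` → successful
  ovulation; ≥2 days below → ovulatory dysfunction; no PdG rise at all →
  anovulatory; <3 days tested → indeterminate.
* **Ovulation Score** — 100 when all four days are sustained, 10 when none
  is, with documented 20–90 bands in between.
* **FSH screen** — any day with `FSH > 10 mIU/mL` (strict) flags possible
  diminished ovarian reserve.

Calibration support covers both lateral-flow geometries: sandwich-format
lines (LH) fit `intensity = m·c + b`, competitive-format lines (E1G, PdG)
fit `intensity = A·e^(−kc)` by least squares on log intensity, with
replicate %CV, 3-SD acceptance bounds and ≥90 % pass-rate gates.

## Worked example

```r
library(cyclemap)

rec <- cycle_record("A102",
  cycle_day = c(5, 7, 9, 10, 11, 12, 13, 14, 15, 16, 17, 21, 22, 23, 24),
  e1g = c(50, NA, 100, 120, 140, 230, 250, 240, 200, 160, 140, 120, 110, 100, 90),
  lh  = c(4, NA, 5, 6, 8, 10, 35, 30, 12, 9, 7, 6, 5, 5, 5),
  pdg = c(0.7, NA, 0.7, 0.8, 0.8, 0.9, 1.0, 1.2, 2.8, 4.5, 6.0, 8.0, 7.5, 7.0, 6.5),
  fsh = c(6, 8, 7, rep(NA, 12)))
map_cycle(rec)
#> Cycle map: subject A102
#>   E1G rise: day 12 | LH peak: day 13 (1 surge episode) | PdG rise: day 15
#>   Fertile window: 3 days (E1G->LH 1, LH->PdG 2)
#>   Classification: successful_ovulation | Ovulation Score: 80
#>   FSH: normal (max 8 mIU/mL on day 7)
```

E1G first clears `max(175, 1.5 × 50)` on day 12; LH exceeds 25 on days
13–14, so peak fertility is day 13; PdG reaches 2.5 on day 15, confirming
ovulation and closing a 3-day fertile window (1 + 2). Implantation-window
PdG (days 20–23 post-peak+7…+10) was tested on 3 of 4 days, all sustained
above 5 µg/mL → successful ovulation; the score is 80 (base 70 for three
sustained days, +10 for a mean of 7.5 µg/mL). FSH never exceeded
10 mIU/mL.

Downstream:

```r
coh  <- simulate_cohort(table3_preset(), seed = 7)   # 38 ovulatory + 2 anovulatory
maps <- lapply(coh$records, map_cycle)
summarize_cohort(maps)                               # means, ranges, t-based 95% CIs
cat(render_report(maps[[1]], format = "markdown"))   # per-cycle report
```

A thin CLI (`exec/cyclemap`, or `cyclemap_cli()` in-process) chains the
same steps: `simulate`, `map`, `score`, `cohort`, `qc`.

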