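---
title: "Methods: chart-based CVD risk screening, decision rules, and field analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chart-based CVD risk screening, decision rules, and field analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdscreen)
```

This vignette is the package's own account of its methods: the risk model
and its assumptions, the decision rules and how ambiguities in them were
resolved, the analytics estimators and their numerical choices, what the
synthetic generators emulate (and what they do not), and the design
decisions that were genuinely open.

## The risk model

Absolute 10-year CVD risk is a *categorical lookup*, not a fitted
equation. A chart maps the cell
(diabetes, gender, smoking, age band, SBP band, and — on the
high-information variant — total-cholesterol band) to one of five ordered
bands: <10%, 10–<20%, 20–<30%, 30–<40%, ≥40%. This mirrors the
colour-coded wall charts used by screening programmes in low-resource
settings, where cholesterol assays are often unavailable: when a profile
carries total cholesterol the HI chart is used, otherwise the LI chart.
Consequences of the lookup structure:

* **Banding convention.** Edges are half-open with the lower edge
  inclusive and the top band closed above: SBP 159 → 140–159, 160 →
  160–179; age 49 → 40–49, 50 → 50–59. A single consistent tie-break
  avoids boundary ambiguity; tests sweep every edge.
* **Units.** The data model stores cholesterol and glucose in mg/dL, as
  point-of-care devices report them; chart TC edges are mmol/L. The
  standard molar conversions are applied at lookup (TC: 38.67 mg/dL per
  mmol/L; glucose: 18.016).
* **Under-age participants.** Charts start at 40. Screening tools accept
  younger walk-ins, so ages below 40 are clamped to the lowest band and
  the result carries an `age_below_chart_range` warning flag rather than
  an error.
* **Representative blood pressure.** Automated cuffs transmit three
  readings. The representative pair discards the first reading (which
  typically runs high) and averages the last two, rounded to integer
  mmHg; with fewer than three readings, all are averaged. The summarized
  SBP feeds the chart.
* **Diabetes input.** The chart's diabetes axis is resolved as: history
  of diabetes, fasting glucose ≥126 mg/dL, or random glucose
  ≥200 mg/dL — the standard diagnostic cut-offs. Using measured glucose
  in addition to history lets a screening encounter detect undiagnosed
  diabetes, which is common in these cohorts.

The engine is chart-agnostic. Published chart cell values are copyrighted
tables and are not shipped; the packaged fixtures are **synthetic**,
built from an additive score over the cell's factors and therefore
monotone in every input, which the tests exploit. The HI fixture is
arranged so that a diabetic male smoker in the lowest age band with SBP
160–179 and TC <5 mmol/L sits in the ≥40% band while the same cell one
SBP band lower sits in 20–<30% — the transition a point-of-care risk
projection meter illustrates when it shows the effect of a ~10 mmHg
systolic reduction. Users with access to a licensed chart transcribe it
into the CSV dialect (`load_chart()` verifies totality: every cell of the
band grid exactly once).

## Decision rules

Sub-conditions are literal transcriptions of the screening rules:
clinically high risk (SBP ≥160 or DBP ≥100 or TC ≥320 or LDL ≥240 mg/dL
or TC/HDL >8; missing lipids never trigger), impaired fasting glucose
(fasting 110–<126 mg/dL **or a history of diabetes**), weight status
(BMI ≥30 obese, 25–<30 overweight, applied to the unrounded BMI),
hypertension (≥140/90 or history).

Two ambiguities deserve prominence:

* **The IFG rule conflates IFG with diabetes.** Its history arm makes
  every participant with known diabetes "IFG". We implement the rule as
  printed because the referral logic treats diabetes and IFG identically
  ("refer if diabetes or IFG is present"), so the conflation is
  inconsequential for plans, but `sub_conditions()` exposes both flags so
  analysts can distinguish them.
* **Clinically high risk escalates the management tier.** Field reports
  of such programmes group "risk >30%, or clinically high risk, or prior
  CVD" as the high-risk denominator, so the effective management tier is
  `high` under any of the three, triggering referral, the 3-month
  re-screening interval (configurable 3–6) and all three medication
  classes. Whether clinically-high-risk alone triggered all medication
  classes in any particular deployment is not documentable; treating it
  so is the conservative choice and a one-line edit in the rules file.

The lower tiers follow the printed decision table: 20–<30% — yearly
screening, referral, BP-lowering if ≥140/90, lipid-lowering if diabetes
or SBP ≥160 or TC >200 or LDL >120 mg/dL; 10–<20% and <10% — screening
every 2 / 5 years, referral when diabetes or IFG is present (or diabetic
history with SBP ≥160), BP-lowering if (diabetes and ≥140/90) or SBP
≥160, lipid-lowering if diabetes or SBP ≥160. The whole table ships as
YAML (`inst/extdata/rules_default.yaml`) interpreted by a small
condition vocabulary, so a programme can re-encode its own guideline
without touching code; `load_rules()` validates completeness. Referral
reasons use a two-label vocabulary (`high_cvd_risk` for band/tier-driven
referrals, `ifg` attached whenever the IFG flag holds); a diabetes-driven
referral without the IFG flag (possible only for glucose-diagnosed
diabetes without history) carries no reason label rather than a third,
undocumented one. Unknown tri-state history answers are treated as "no"
by the rules — conservative for medication triggers — while the stored
record keeps the `NA` for audit.

## Analytics estimators

* **Timing.** Only complete (step-4 finished), sequential procedures
  enter timing summaries. A procedure is *non-sequential* when its span
  overlaps another encounter of the same worker — the interleaving that
  makes click-stream durations meaningless; both members of an
  overlapping pair are excluded. Medians and IQRs use linearly
  interpolated quartiles (R type 7), IQR = Q3 − Q1.
* **Sequential bootstrap CI.** At each procedure index k the mean
  completion time is bootstrapped from procedures 1..k (resampling with
  replacement, default 2000 replicates), showing how a worker's estimated
  mean and its uncertainty evolve as she accrues procedures. Intervals
  are percentile intervals with *expanded* levels
  (`pnorm(sqrt(k/(k-1)) * qt(alpha/2, k-1))` in place of `alpha/2`,
  Hesterberg 2015): the plain percentile interval is systematically
  narrow at the sample sizes a field worker accrues (measured coverage
  ≈92.8% at k = 20 for a nominal 95% interval), while the expanded levels
  restore ≈94.6% coverage. `expand = FALSE` gives the unadjusted
  interval. Everything is reproducible bit-for-bit given a seed, which
  stochastic entry points require explicitly.
* **Rates.** Bluetooth adoption and section-dissemination rates share the
  same denominator — that worker's complete sequential procedures. Raw
  fractions are authoritative; nearest-integer percentages are attached
  because usage tables print them that way.
* **Glucose reconciliation.** Manually entered values are matched to
  glucometer-memory readings one-to-one, greedily by smallest absolute
  time gap within a ±10-minute window (the window is configurable; "taken
  at the same time" has no canonical width). Matched pairs with non-zero
  discrepancy are errors; median/IQR are computed over non-zero
  discrepancies, and unmatched entries are reported separately rather
  than counted. Matching one glucometer per worker is the intended use;
  pooling devices across workers invites cross-matches whenever two
  workers screen within the window of each other.

## The synthetic generators

The generators exist so that every analysis in the package is exercisable
and testable without field data; their defaults encode the study
conditions they emulate.

* **Cohort.** A two-stratum mixture: a low-risk majority (SBP ~122 mmHg,
  TC ~180 mg/dL, low smoking and history prevalences, but a sizeable
  impaired-fasting-glucose subgroup) and an elevated stratum (SBP ~172,
  TC ~235, diabetes history 35%, some prior CVD) mixed at a target
  high-risk fraction of 0.34, reproducing the bimodal risk distribution
  rural screening programmes report, with just over half of participants
  meeting some referral condition. Ages are normal (mean 51.4, SD 13.1)
  truncated at 40. After generation the cohort is classified under the
  shipped charts; if the achieved high-risk fraction misses the target by
  more than 5 points the cohort is redrawn (bounded retries, then a
  warning). The generator is *not* demographically realistic beyond the
  moments the analyses need — no household structure, no geography, and
  marginals (not joint distributions) were calibrated; passing tests
  say the pipeline recovers what the generator planted, not that the
  generator matches any real population.
* **Event streams.** Step times are lognormal — positive and
  right-skewed, matching the wide IQRs field timing shows — with per-step
  `sdlog` chosen to reproduce observed IQR/median ratios
  (0.63/0.95/0.77/0.87 for the four steps). Learning is a geometric decay
  (default 0.97 per procedure) applied to every duration median, the
  simplest curve consistent with the observed downward trend. Baseline
  medians are start-of-study values: defaults are the observed
  *study-wide* step medians (157/68/633/90 s) inflated by the mid-study
  decay factor 1/0.97^10, so a simulated ~20-procedure study lands near
  the observed medians. Bluetooth adoption is logistic in the procedure
  index (workers warm to the feature); Bluetooth BP acquisition is drawn
  shorter than manual triple entry. Section visits are independent
  Bernoulli draws. Manual glucose entry is corrupted with configurable
  probability by transposing two adjacent digits or slipping one digit by
  ±1–5 — the two classic transcription errors, giving the wide error
  range such audits report. Simulated totals run ~2–4 minutes below
  observed totals because real procedures contain overhead outside the
  four step spans that the generator only partially models.
* **Glucometer memory.** One record per measurement at the true value,
  90 s before the manual entry — measurement precedes transcription —
  hence inside the procedure window, and deterministic given the stream.

Determinism is strict: cohort, events and memory are byte-identical for
identical parameters (seeds are mandatory, scoped with
`withr::with_seed` so user RNG state is untouched).

## Numerical and interface choices

* Validation ranges (age 18–120 y; SBP 60–300, DBP 30–200 mmHg; glucose
  20–600, TC 50–500, HDL 10–150, LDL 20–400, TG 20–1000 mg/dL; height
  100–250 cm; weight 20–250 kg) are wide clinically plausible bounds —
  screening validation should reject transcription garbage, not unusual
  patients — and are overridable per run.
* BMI is reported to 1 decimal; category edges apply to the unrounded
  value to avoid boundary artefacts.
* Encounters serialize as nested JSON (auditable one-participant
  records); cohorts and logs as flat CSV. Every writer's output is
  accepted by its reader, a property the tests enforce on generated data.
* The CLI is a thin Rscript over the exported functions with a stable
  exit-code contract (0 success, 1 computational failure, 2 invalid
  input) and refuses stochastic work without an explicit seed.

## Problem sizes in the shipped checks

The test suite and acceptance script are sized for quick desk runs while
still being exhaustive where exhaustiveness is the point: the chart
oracle covers every fixture cell (640 HI + 128 LI) plus full boundary
sweeps; the decision-table oracle a 4,320-case discretized grid; bootstrap
coverage uses 1,000 replicates at n = 20; generator recovery uses one
500-procedure stream for section probabilities and 200 replicate
28-procedure streams for the learning rate; the acceptance script screens
a fresh 292-person cohort and simulates an 11-worker, 227-procedure
study.

## Known limitations

* The shipped charts are synthetic; absolute bands from them are
  meaningful only relative to each other. Real use requires transcribing
  a licensed chart.
* The rule engine's condition vocabulary covers the shipped decision
  table; exotic guideline conditionals would need new primitives (a
  deliberate trade against arbitrary code in config files).
* Non-sequential detection needs encounter spans; a log whose encounters
  never complete yields no timing rows at all.
* The Likert instrument is the four-point scale only; no reverse-coded
  items, no per-question structure.
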