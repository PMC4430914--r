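# cvdscreen

Chart-based cardiovascular risk screening, point-of-care decision support,
and field-evaluation analytics for community health-worker programmes.

Door-to-door screening programmes in low-resource settings put absolute
cardiovascular disease (CVD) risk assessment in the hands of minimally
trained village health workers: a worker records demographics, medical
history and measured risk factors on a tablet, the tool assigns a 10-year
absolute risk category from colour-coded lookup charts, and rule-based
decision support turns that category into referral, medication and
next-visit recommendations. `cvdscreen` re-implements that pipeline as a
tested, reusable R package, together with the analytics used to evaluate
such a deployment from its click-stream logs, and seeded synthetic
generators so that every analysis is runnable without field data.

## What it computes

**Risk categorisation.** A profile (diabetes status, gender, smoking, age,
systolic blood pressure, and total cholesterol when known) is looked up on
a categorical risk chart with five ordered bands (<10%, 10–<20%, 20–<30%,
30–<40%, ≥40%). The high-information (HI) chart variant is used when total
cholesterol is available, the low-information (LI) variant otherwise.
Continuous inputs are banded half-open (age 40–49 / 50–59 / 60–69 / 70+;
SBP <140 / 140–159 / 160–179 / ≥180 mmHg; TC <5 / 5–6 / 6–7 / 7–8 / ≥8
mmol/L, converted from mg/dL with the standard divisor 38.67). The engine
is chart-agnostic: any chart in the documented CSV dialect loads with
`load_chart()`; the package ships clearly labelled **synthetic** fixture
charts (`synthetic_chart()`), not transcriptions of any published chart.

**Decision support.** Sub-conditions follow standard screening rules:
clinically high risk (SBP ≥160, DBP ≥100, TC ≥320 mg/dL, LDL ≥240 mg/dL,
or TC/HDL >8), impaired fasting glucose (fasting 110–<126 mg/dL or a
diabetes history), weight status (BMI ≥25 overweight, ≥30 obese),
hypertension (≥140/90 or history), diabetes (history, fasting ≥126, or
random ≥200 mg/dL). `management_plan()` applies a data-driven decision
table (shipped as editable YAML): the high tier (≥30% band, prior CVD, or
clinically high risk) is referred, re-screened in 3 months and offered all
three medication classes; lower tiers get 12/24/60-month screening
intervals with conditional BP-lowering and lipid-lowering therapy and
referral when diabetes or impaired fasting glucose is present.
`project_risk()` computes counterfactual bands ("what if SBP dropped by
10 mmHg") for risk communication.

**Field analytics.** From a timestamped click-event log:
procedure/step timing medians and IQRs, sequential bootstrap confidence
intervals for the mean procedure time (at each procedure index k,
resampling procedures 1..k), Bluetooth-adoption and
recommendation-dissemination rates, reconciliation of manually entered
glucose values against glucometer memory (greedy nearest-in-time
one-to-one matching), and Likert usability summaries.

**Synthetic data.** `generate_cohort()` draws a bimodal screening cohort
(low-risk majority plus an elevated stratum) targeting a configurable
high-risk fraction; `generate_event_stream()` emits per-worker click
streams with lognormal step times, geometric learning-curve decay,
logistic Bluetooth adoption, Bernoulli section visits and digit
transposition/slip errors in glucose entry, returning ground truth
alongside; `generate_glucometer_memory()` yields the matching meter
records.

## Worked example

```r
library(cvdscreen)

p <- risk_profile(age = 33, gender = "male", smoker = TRUE,
                  sbp = 160, dbp = 89, tc = 176,
                  history = medical_history(past_diabetes = TRUE))
cfg <- run_config()   # shipped synthetic charts + default rules

assess_risk(p, cfg$chart_li, cfg$chart_hi)
#> <risk_assessment> 10-year CVD risk >=40% [R40_PLUS], HI chart
#>   warnings: age_below_chart_range

sub <- sub_conditions(p)
management_plan(assess_risk(p, cfg$chart_li, cfg$chart_hi), sub, p)
#> <management_plan> tier high (band R40_PLUS)
#>   referral: YES (high_cvd_risk, ifg)
#>   next CVD screening in 3 months
#>   diabetes screening advised
#>   medications: bp_lowering, lipid_lowering, antiplatelet
#>   advice: smoking_cessation, nutrition, lifestyle

pr <- project_risk(p, list(sbp = -10), cfg$chart_li, cfg$chart_hi)
as.character(c(pr$before$band, pr$after$band))
#> [1] "R40_PLUS" "R20_30"
```

The 33-year-old diabetic male smoker at 160/89 mmHg sits in the top band
(his age is below the chart range, so he is clamped to the lowest age band
and the result carries a warning flag); he is clinically high risk (SBP
arm) and his fasting glucose history also flags impaired-glucose referral.
Lowering systolic pressure by 10 mmHg would move him from the ≥40% band to
20–<30% — the comparison a point-of-care risk projection meter displays.

Analytics on a deterministic demonstration log:

```r
procs <- build_procedures(field_demo_log())
subset(dissemination_rates(procs), user_id == "npB1")
#>   user_id         section n_visited  n      rate rate_pct
#>      npB1      risk_meter        22 28 0.7857143       79
#>      npB1 recommendations        27 28 0.9642857       96
#>      npB1      next_visit        26 28 0.9285714       93
```

i.e. this worker opened the risk meter in 79% of her 28 completed
procedures, the recommendations screen in 96%, the next-visit screen in
93%. A shell wrapper with the same functionality ships in
`inst/cli/cvdscreen.R` (`assess`, `batch-screen`, `analytics <sub>`,
`simulate <sub>`, `validate-chart`, `validate-rules`; exit codes 0/1/2 for
success / computational failure / invalid input).

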