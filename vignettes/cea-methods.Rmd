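---
title: "Methods: societal cost-effectiveness analysis of telemonitoring in IBD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: societal cost-effectiveness analysis of telemonitoring in IBD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceatrial)
```

## The evaluation problem

`ceatrial` implements a trial-based economic evaluation from the societal
perspective for a three-arm, 24-week parallel trial in complex inflammatory
bowel disease (IBD): web-based telemonitoring versus nurse-assisted
telephone care versus standard face-to-face follow-up, 21 patients per arm.
Patients enter at initiation of immunosuppressants and/or biologic agents,
i.e. with active disease, and mostly improve over the follow-up. The
evaluation asks what each follow-up strategy costs society per patient and
what it returns in health, measured two ways:

* **cost-effectiveness**: the increase over 24 weeks in the proportion of
  patients in clinical remission (Harvey–Bradshaw index ≤ 4 for Crohn
  disease; Simple Clinical Colitis Activity Index and partial Mayo score
  each ≤ 2 for ulcerative colitis);
* **cost-utility**: QALYs from the EQ-5D utility index measured at baseline
  and week 24.

For two strategies A and B the incremental cost-effectiveness ratio is
ICER = ΔC/ΔE. Sampling uncertainty is characterised by a stratified
nonparametric bootstrap run across multiply imputed datasets, summarised as
percentile intervals, cost-effectiveness-plane quadrant probabilities, and
cost-effectiveness acceptability curves (CEACs) over a willingness-to-pay
(WTP) range of €0–20,000.

## Cost model

All computation is in euros; US dollars are a report-time conversion
(`eur_to_usd = 1.09465`). Costs are not discounted at this horizon, and
lost productivity is valued by the human-capital approach (gross wage for
all time lost). Three categories:

**Health care.** Resource counts over 24 weeks (emergency visits,
outpatient visits, hospital days, surgical hospital days, telephone
contacts by provider type) times official unit rates. Telemonitoring
contacts have no official tariff; their rate is constructed as provider
minutes per contact (8 min) times provider salary per minute (€0.21 nurse,
€0.38 physician), giving €1.68 and €3.04 per contact.

**Equipment.** Platform rental at €3.99 per patient-month for the 6-month
horizon (€23.94 per telemonitoring-arm patient); zero elsewhere.

**Productivity and leisure.** From the Work Productivity and Activity
Impairment (WPAI) questionnaire, 7-day recall, assessed at weeks 0, 12 and
24:

* absenteeism: hours of work missed (Q2) × the sex- and age-specific gross
  hourly wage, employed patients only;
* presenteeism: percent impairment while working (Q5) × hours actually
  worked (Q4), capped at hours worked (losing more hours than one worked is
  meaningless), valued at the same wage;
* absence for in-person visits: 3.3 hours per outpatient or emergency
  visit, at the wage. Telephone contacts cost their call duration
  (configurable, default 10 min) at the wage, on the assumption that calls
  fall in working hours. Patient time in telemonitoring contacts is assumed
  to fall outside office hours and is valued at the leisure rate (€9.18/h,
  default 5 min per contact);
* social-activity impairment: Q6 percent impairment × a weekly base of
  leisure hours at risk × the leisure rate. The weekly leisure-hours base
  is configuration with default 0, because no defensible default exists at
  this granularity and the packaged calibration targets a cost structure in
  which diffuse leisure loss is not separately priced; setting
  `leisure_hours_base > 0` activates the category.

Because WPAI has a 7-day recall but assessments sit 12 weeks apart, weekly
quantities are expanded **piecewise-constant** over the preceding interval:
the week-12 response covers weeks 1–12, the week-24 response weeks 13–24
(`interval_expand()`). The baseline response describes the pre-study week
and is not costed. This is the simplest defensible expansion; it is
isolated in one operation so an alternative (e.g. linear interpolation)
can be swapped in without touching anything else. The same expansion is
used for weeks in remission.

Visit- and call-absence time is valued at the wage for *all* patients,
while Q2/Q5 losses apply to employed patients only: the former is lost time
with a market opportunity cost regardless of employment in this costing
convention, and arm-level means computed this way are consistent with the
calibration targets.

Each patient yields a `CostBreakdown` row whose sum invariants
(`total = total_healthcare + total_productivity`, with equipment inside
health care) are enforced and property-tested: costs are additive,
linear in the unit rates (an inflation multiplier in the unit-cost table
scales everything uniformly, default 1), and monotone in resource use.

## Effect model

Remission is classified per disease; for ulcerative colitis, when both
indexes are recorded both must be ≤ 2, and when only one is recorded the
recorded one decides (the instruments are used jointly and conflicts are
not otherwise adjudicated). The group effect for cost-effectiveness is the
remission-increase proportion (remitters at week 24 minus remitters at
baseline, over n).

QALYs follow the *gained-utility* convention: per patient,
`(EQ-5D week 24 − EQ-5D week 0) × 0.5 years`. With median improvements of
0.184 (control) and 0.175 (telephone/telemonitoring) this yields the
worked values 0.092 and 0.088 QALYs. An area-under-the-curve alternative
(`convention = "auc"`) is available for sensitivity analyses; the gained
convention is the default because it reproduces the worked arithmetic and
because baseline imbalance in utilities otherwise leaks into the
incremental effect. Group summaries use the median for worked-example
reproduction and the mean inside the bootstrap, which resamples patients.

## Missing data

Week-12/24 scores, utilities, WPAI responses and (in principle) resource
counts may be missing; the default synthetic trial drops the week-24
patient-reported assessments of 3 of 21 telemonitoring-arm patients while
registry-derived resource counts remain observed. Imputation is an
Amelia-family **bootstrap-EM** multiple imputation (`m = 5` by default):
for each imputation the records are resampled, the multivariate-normal MLE
is fitted by EM on the resample (ridge prior toward a diagonal covariance,
default weight 0.5 pseudo-observations per variable, stabilises the
63-patient fit), and missing cells of the original records are drawn from
the conditional normal given their observed cells. Arm, disease, age and
employment enter as fully observed covariates so imputation respects the
group structure (the dropout pattern is arm-dependent).

Numerical choices: counts and hours are modelled on the `log1p` scale and
back-transformed (counts rounded to non-negative integers and capped,
percentages clipped to [0, 100], utilities to [−1, 1]); the two
disease-specific activity-index families are modelled through one
*activity margin* (score minus its remission threshold), which is what the
remission classification consumes, and mapped back to scores after the
draw; observed cells are never altered. The `method_tag` on every
imputation set records this variant. Exact settings of the original
Amelia-based analysis are not recoverable, so these defaults are
documented rather than claimed to match.

Point estimates are pooled across imputations by Rubin's rules: pooled
estimate = mean of estimates; total variance = within + (1 + 1/m) ×
between. Property tests check the closed-form example (estimates 1…5 with
zero within-variance pool to 3 with total variance 3.0), recovery of
complete-data means under 20% MCAR, and nominal coverage of the pooled 95%
intervals over 200 simulation replicates.

## Bootstrap engine

For each imputation and each of B replicates (default 1000, so 5000 draws),
patients are resampled with replacement *within each arm* (n = 21 per arm),
group summaries recomputed, and one (ΔC, ΔE) pair emitted per effect
measure. Summaries:

* **median ICER and 95% percentile interval** over the pooled m × B draws
  with defined ICER (ΔE = 0 draws are excluded from ratio summaries but
  retained for the plane and CEAC); the flattened pooling matches how the
  bootstrapped medians are reported, while Rubin pooling applies to the
  point estimates of means;
* **quadrant probabilities** of the cost-effectiveness plane; the
  south-east quadrant (ΔE > 0, ΔC < 0) is dominant. Boundary draws are
  resolved by strict inequalities (ΔE = 0 counts as not more effective,
  ΔC = 0 as not cost saving) so the four probabilities sum to exactly 1 —
  a measure-zero choice for continuous costs but a deterministic one;
* **CEAC** by the net-monetary-benefit criterion: at each λ the probability
  that λΔE − ΔC > 0. NMB rather than an ICER-threshold rule because ICER
  thresholds are sign-ambiguous when ΔE < 0. At λ = 0 the curve equals
  P(ΔC < 0) exactly; when a majority of draws has ΔE < 0 the curve
  decreases with λ toward P(ΔE > 0), which is exactly the behaviour the
  QALY-based curves show when most simulations involve no health gain.

Random numbers: one master seed; each imputation gets a derived substream
and replicates consume it sequentially, so enlarging B extends the draw
sequence without reshuffling earlier draws, reruns are bit-identical, and
sensitivity scenarios automatically share resample indices (common random
numbers). The engine is tested against three oracles: the CLT (draw means
versus known cohort means), the closed-form normal CEAC
Φ((λμ_E − μ_C)/√(λ²σ_E² − 2λσ_CE + σ_C²)), and exhaustive enumeration of
all with-replacement resamples on 4-patient arms.

## Sensitivity scenarios

One-way cost-driver scenarios scale the health-care (including equipment)
and the productivity/leisure categories by independent multipliers,
typically a ±60% grid, and recompute CEACs with common random numbers so
that curve differences isolate the cost scaling. Both one-at-a-time and
crossed variation are supported (`scenario_grid()`), since "independently"
admits either reading. With equal multipliers on both categories every
ΔC draw scales by that factor, so its sign — and hence CEAC(0) — is
invariant, which the tests exploit.

## Synthetic trial generator

No patient-level data are distributable, so `generate_trial()` produces
cohorts whose *arm-level* summaries match the published group summaries;
per-patient values are synthetic by construction and the generator's
defaults are the study conditions (21 per arm, three arms, 24 weeks).

Structure: each patient carries a latent severity `z`; visit-level
severities are correlated with `z` (ρ = 0.6) and drive remission status,
activity scores, EQ-5D, WPAI impairment, calprotectin and (through a
mean-one multiplier) resource counts. Remission status is obtained by
thresholding the severity quantile at the target arm probability, which
makes arm remission proportions exact in expectation and the score-severity
link monotone. Week-12 remission probabilities are chosen so that expected
weeks in remission match the published means under the piecewise-constant
expansion. EQ-5D is clip-normal on [−1, 1]; the clip produces the ceiling
mass at 1.0 that makes week-24 medians 1.00. Counts use negative-binomial
sampling where the published SD exceeds the mean (zero-inflated for
surgical stays: rare but multi-day), Poisson for rare equidispersed events,
and a discretised normal for scheduled outpatient visits, which are
strongly underdispersed (mean 6.30, SD 0.57) and outside what any
(zero-inflated) negative binomial can produce.

Calibration: count means/SDs, remission probabilities, employment and
disease mix are set directly from the published summaries; the EQ-5D
clip-normal means and the follow-up WPAI hour/impairment means were tuned
once by moment matching at n = 20,000 per arm against arm mean utilities
and mean total societal costs (€1066 / €992 / €807), then frozen. The
published per-category productivity rows are not jointly consistent with
the published productivity totals, so the calibration targets the totals,
which are what drive incremental costs and ICERs; generated
absenteeism/presenteeism category means therefore sit below the published
category rows. Baseline WPAI reflects active disease (high impairment) but
is not costed, so it is calibration-neutral.

What the generator does *not* emulate: real wage heterogeneity beyond
sex × age bands, within-patient serial cost correlation beyond the single
latent factor, informative (MNAR) dropout, and any patient-level feature
of the original cohort. Passing tests therefore demonstrate that the
pipeline is correct and calibrated at the group level, not that it
reproduces the original patient-level analysis.

## Problem sizes and runtime choices

Defaults follow the study design: m = 5 imputations, B = 1000 replicates
(5000 draws per contrast), WTP grid €0–20,000 in steps of 500. The test
suite uses smaller B (40–500) for pipeline plumbing, B = 5000–20,000 where
an oracle comparison needs Monte-Carlo headroom, n = 10,000–20,000 patients
per arm for calibration checks, and 200 replicates for interval coverage;
these sizes give tolerances of three Monte-Carlo standard errors
throughout.

## Known limitations

* The imputation model is multivariate normal with transforms; strongly
  non-normal cells (the EQ-5D ceiling) are handled by clipping, which is
  adequate for means but approximate in the tails.
* The piecewise-constant WPAI expansion attributes the full 12-week
  interval to a single 7-day recall; any within-interval recovery dynamics
  are invisible to it.
* ICER medians and percentile intervals are reported without Fieller or
  BCa corrections, and no cost-effectiveness frontier across the three
  arms is computed — contrasts are pairwise.
* The EQ-5D tariff itself is out of scope: utilities arrive pre-computed.
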