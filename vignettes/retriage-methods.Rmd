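---
title: "Methods: quantifying suboptimal re-triage in a regionalized trauma system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying suboptimal re-triage in a regionalized trauma system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retriage)
```

## The problem

Seriously injured patients (injury severity score, RISS, above 15) are often
under-triaged from the field to a nontrauma or level III/IV trauma center.
*Re-triage* is the emergent correction of that error: transfer from the
sending center's emergency department to a second acute-care hospital within
one day of presentation. The transfer is **optimal** when the receiving
hospital is a level I/II trauma center and **suboptimal** when the patient
lands at a second nontrauma or level III/IV center. This package quantifies
suboptimal re-triage from linked administrative ED and inpatient discharge
records over a geographic hierarchy — state, regional trauma coordinating
committee (RTCC), local EMS agency (LEMSA), and sending center — models its
predictors with a mixed-effects logistic regression, draws the transfer
network, and searches for alternative level I/II destinations under a
ground/air transport-time rule.

Real statewide discharge data of this kind are nonpublic. The package is
therefore built around a synthetic administrative-data generator with known
ground truth; every downstream stage is validated against that truth.

## Encounter linkage and the cohort

Administrative records carry a pseudonymous record linkage number (RLN) and
date-only stamps — no admission or discharge times. Linkage is consequently
coarse and deterministic:

* **Deduplication.** Rows identical on (RLN, facility, record kind, admit
  date, discharge date) collapse to their first occurrence before linkage.
* **Pairing.** An ED record pairs with an inpatient record sharing its
  non-missing RLN at a *different* facility when the receiving admission is
  0 or 1 days after the sending ED discharge. The 1-day window deliberately
  includes midnight-spanning transfers (late-night ED presentation, early
  morning admission), which date-only data would otherwise split; it is the
  admit-minus-discharge difference because those are the two dates the files
  reliably carry. Gaps of 2+ days are *interfacility transfers* — scheduled
  moves to specialized care, not emergent re-triage — and are routed to the
  under-triaged stratum, flagged. When several inpatient candidates qualify,
  the earliest admission wins, ties broken by lexicographic facility id, so
  linkage is order-independent.
* **Exclusion cascade.** Rules are applied in a fixed, published order, each
  removal attributed to the first rule that fires and logged in a ledger:
  age 18–89 (the upper cap avoids identifiable extreme ages); injury
  diagnosis present; RISS strictly greater than 15; no burn injury (burn
  centers are a separate referral system); sending facility a short-term
  acute-care hospital; receiving admission not elective; receiving facility
  short-term acute (rehabilitation, psychiatric and long-term facilities are
  not re-triage destinations); sending ED disposition not "expired", "left
  against medical advice" or "rehabilitation with planned readmission"; and
  finally, patients field-triaged directly to a level I/II center. Pair
  formation itself is purely RLN/date-based: keeping every facility-level
  criterion inside the cascade makes the partition exact — each deduplicated
  ED encounter ends in exactly one of cohort pair, under-triaged stratum, or
  excluded-with-reason, and the ledger is conservative by construction. The
  rule *order* is a design choice (ledger counts are order-dependent; the
  final cohort is not), fixed so ledgers are comparable across runs.

Trauma designation is annual, so each facility's level is resolved in the
calendar year of its own record date (sending discharge year, receiving
admission year).

## Labeling, aggregation, and covariates

Optimality is a pure function of the receiving level in the event's year —
distance is never consulted; a 300-mile transfer to a level I center is
optimal. Rates are aggregated per unit and year with three conventions worth
stating: units with zero re-triages report an *undefined* (NA) rate, never
zero; share-of-state columns divide each unit's suboptimal count by the
statewide total of the same year stratum; percentages are reported to one
decimal for report parity.

Covariate encoding is deterministic: age into 18–24 (reference) then
10-year bands capped at 85–89 by the inclusion rule; RISS into 16–25 versus
>25 (25 stays in the reference band, following the published banding);
raw payer codes into self-pay/private/Medicare/Medicaid/other, with
managed-care plans mapped to private *except* plans reported without a payer
("HMO-unspecified" and kin), which are kept as their own
managed-care-unspecified category because such records can hide
Medicare-managed-care patients and folding them anywhere would be a silent
misclassification. When several body regions are flagged on one encounter, a
fixed precedence (TBI > torso > other head/face/neck > extremities > other)
picks the reported region; published tables show single categories without
stating a precedence, so this one is documented rather than asserted as
faithful.

## The synthetic generator

`sim_config()` defaults are the study conditions wherever the source system
states them, and one-time realistic choices where it does not:

| parameter | default | basis |
|---|---|---|
| `years` | 2009–2018 | the ten data years |
| `p_retriage_within_1day` | 0.206 | 8,882 of 43,066 low-level presentations transferred within one day |
| `p_suboptimal_given_retriage` | N .220, BA .375, C .104, SE .202, SW .688 | pooled per-RTCC observed rates |
| `p_missing_rln` | 0.25 (ED), 0.125 (inpatient) | reported identifier missingness (~25% ED, 11–14% inpatient) |
| covariate marginals | ~ cohort table | majority elderly, 59% male, 74% white, falls dominant |
| `p_duplicate` | 0.05 | unreported ("varied by year"); a one-time realistic choice |
| `p_undertriage_to_low` | 0.85 | most generated patients present to low-level centers; the direct-to-I/II minority exists to fire the field-triage exclusion |
| edge-case rates | 1–5% | enough mass that every exclusion rule fires at test sizes |
| `los_lambda` | 4 | Poisson LOS with median 4 days, matching the published median |

Suboptimality is assigned on the logit scale: per-RTCC base rate, plus
optional covariate log-odds (`covariate_effects`, names validated against
the covariate vocabulary), plus sending-center and year random intercepts
(`center_sigma`, `year_sigma`, default 0 so the marginal rates equal the
configured probabilities exactly). A single integer seed determines all
output; identical configs are byte-identical.

What the generator does **not** emulate: ICD code strings (RISS is consumed
as a field; its derivation from diagnosis codes is upstream), prehospital
vitals, transport logistics, seasonality, or any claim of joint demographic
realism — marginals are independent draws. Passing tests therefore
demonstrate the *pipeline's* correctness on data with the right
administrative pathologies (duplicates, missing identifiers, date-only
stamps, every exclusion edge case), not epidemiological fidelity of the
simulated population.

## The mixed-effects model

The suboptimality model is a binomial GLMM with logit link: fixed effects
for age band, sex, race, ethnicity, insurance, mechanism, body region, RISS
band and the sending center's RTCC (reference levels 18–24, male, white,
non-Hispanic, self-pay, all-transport, torso, 16–25, CENTRAL), and random
intercepts for sending center and calendar year. The two groupings are
*crossed*, not nested, because centers persist across years. Year enters as
a grouping rather than a trend — the scientific question is clustering, not
drift — though `model_spec(year_as_trend = TRUE)` provides the fixed-trend
variant. Estimation is lme4's Laplace approximation (`glmer`, bobyqa);
intervals are Wald on the log-odds scale, exponentiated to odds ratios,
matching how such predictor tables are conventionally presented and keeping
the output deterministic. Optimizer non-convergence is a hard error carrying
the diagnostics; coefficients with implausibly large magnitude or standard
error trigger a separation warning naming the term.

`simulate_glmm_dataset()` is the model's oracle: it draws data from known
coefficients and random-intercept variances so recovery can be checked. At
the validation size (n = 20,000 events, 100 centers, 10 years, center SD
0.5, year SD 0.25, 20 seeds) the pooled mean absolute coefficient error is
about 0.12 on the log-odds scale and Wald coverage sits near 94%. Regional
coefficients are the widest: with 20 centers per RTCC, a region effect is
estimated against between-center noise of roughly 0.5·√(2/20) ≈ 0.16, which
dominates their error. With variances forced to zero the GLMM reproduces
plain logistic regression to well under 0.01.

## Transfer network

The directed graph has one edge per ordered sending→receiving pair,
weighted by its share of all re-triages in the selected stratum (weights sum
to 1, and the suboptimal weight share equals the rate table's suboptimal
rate — checked automatically in the pipeline). Edge categories follow the
receiving level: optimal (level I/II, drawn blue), suboptimal to a
nontrauma center (red), suboptimal to level III/IV (green). Weights are
normalized within the selected year because the published network snapshot
is a single-year view; pooling remains available by omitting the year.
Layouts are either geographic (coordinates used verbatim) or
Fruchterman–Reingold with a fixed 500 iterations under a caller seed, so
both are reproducible. GraphML and GeoJSON (great-circle edge lines)
exports carry all attributes.

## Destination optimization

For each suboptimal re-triage the candidate set is every level I/II
short-term acute center operating in the event's year. The transport rule is
two-branch: if any candidate lies within 50 great-circle miles, take the
shortest *ground* time among those; otherwise the shortest *flight* time
over all candidates, at a conservative 120 mph along the straight line
(air transport loses its speed advantage below ~50 miles to dispatch and
ground-leg overheads, which date-only administrative data cannot quantify —
they are deliberately ignored, as is any farther-but-faster ground option
beyond the 50-mile screen). The boundary is assigned to air: exactly 50.0
miles flies. Ties break on lexicographic facility id. A directory with no
level I/II center anywhere yields `resolvable = FALSE` — a data outcome
describing a trauma "desert", not an error.

Ground times come from a pluggable drive-time provider so an external road
router can be adapted in; the built-in fallback is great-circle distance ×
circuity 1.3 at 40 mph, both config-exposed since average road speeds are
not part of the data. The 50-mile screen defaults to great-circle distance
(`screen = "provider"` switches to the provider's road distance where it
reports one). The selected destination is verified against brute-force
enumeration over candidate sets on a thousand random geographies.

## Numerical and degenerate-input conventions

* Dates are `Date` (day resolution) throughout; gaps and lengths of stay are
  integer day differences, same-day = 0.
* Readmission windows are inclusive of day W and exclusive of day 0 (a
  same-day onward transfer is not a readmission); flags are defined only for
  survivors to discharge and are NA — excluded from denominators — for
  in-hospital deaths.
* Odds ratios use the Woolf log-normal interval; any zero cell triggers the
  Haldane–Anscombe 0.5 correction with an explicit flag; a zero margin is an
  error. Chi-square tests are Pearson without continuity correction
  (a reproducible closed form); degenerate margins are errors.
* Undefined rates (zero denominators) propagate as NA, never 0.
* Missing RLNs are explicit NA sentinels, never empty strings; records
  without an RLN can never pair and are counted where they fall in the
  cascade.
* Unknown facility ids, unmapped covariate/disposition codes, and invalid
  configs fail fast with errors naming the offending value.

## Problem sizes used in validation

The shipped validation suite runs the full pipeline at 20,000 synthetic
patients for the partition/conservation and rate-recovery checks, 20 GLMM
recovery fits at n = 20,000 each, 1,000 random geographies for the optimizer
oracle, 1,000 random pairs for the transport rule, and 2,000 replicates for
the chi-square null calibration — sizes at which binomial tolerances (3
standard errors) are tight enough to be meaningful while the whole suite
runs in a few minutes on one core.

## Known limitations

Everything inherited from the data model: no times of day, so sub-day
transfer speed is invisible; identifier missingness deletes pairs roughly at
random here but plausibly not at random in real data (undocumented patients
lack the identifiers entirely); RISS quality is upstream; crude 2×2 odds
ratios for hospital-course outcomes are unadjusted; the fallback drive model
is a circuity approximation, not routing; and synthetic covariates carry no
joint structure, so the GLMM validation demonstrates parameter recovery, not
substantive effect estimates.
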