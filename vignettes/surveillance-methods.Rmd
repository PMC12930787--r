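---
title: "Surveillance methods: rules, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveillance methods: rules, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(neosurv)
```

neosurv implements rule-based surveillance of healthcare-associated
infections (HAI) in very-low-birth-weight and very preterm infants. This
vignette is the package's account of the method: the population and
follow-up model, the episode and classification rules, the metrics and
the standardized infection ratio, the synthetic-data generator used to
validate everything, and the decisions taken where the design was
genuinely open.

## Population and follow-up

An infant enters surveillance when live-born, admitted to the unit within
120 days of birth, and either below 1500 g at birth or born before 32
completed weeks of gestation. Both thresholds are strict: a 1500 g,
32+0-week infant is outside the population; a 1500 g, 31+6-week infant is
inside (the ≥ 1500 g stratum exists exactly for this very preterm
subset). Follow-up runs from admission until death, discharge or
transfer. Short absences — up to 48 hours — do not end follow-up; the
days fully spent absent are simply not patient-days.

With date-granular data, the 48-hour rule needs a convention. We count an
absence of *g* full calendar days strictly between two stays as 24·*g*
hours: a two-day absence (48 h) is bridged, a three-day absence (72 h)
ends the surveillance episode. This is conservative and exactly
reproducible from dates alone. A re-admission after a longer absence is
not covered by the episode; the engine drops those stays with a warning
rather than silently starting a second episode, because re-enrollment
semantics are a network policy, not an engine rule. A day with any
recorded presence counts as a full patient-day ("no minimum time"),
including a same-day admission and discharge.

## Exposure accounting

All denominators are day counts over the surveillance window:

| quantity         | rule                                         | threshold |
|------------------|----------------------------------------------|-----------|
| patient-day      | any presence on the calendar day             | none      |
| device-day       | cumulative device hours on the day           | ≥ 12 h    |
| antibiotic day   | ≥ 1 systemic substance recorded              | any       |
| breast-milk day  | enteral feeding exclusively breast milk      | any amount|
| probiotic day    | oral probiotic given                         | any amount|
| kangaroo day     | skin-to-skin contact hours                   | ≥ 2 h     |

Hours are accepted as fractions and thresholds are `>=` comparisons on
exact values (11.99 h is not a device-day; 12.0 h is). Antibiotic days
are counted both cumulatively (a day on two substances is one antibiotic
day) and per substance (that day contributes one day to each substance).
Exposure rows dated outside the surveillance window — for instance during
a bridged absence — are ignored with a warning rather than rejected,
since they are well-formed data that merely fall outside the denominator.

## Episodes and classification

Findings (clinical, laboratory, imaging, surgical evidence) and
microbiology results are *elements*. Within one patient and body system,
elements chain into an episode while the gap to the previous element is
at most `episode_max_gap_days` and the overall span stays within
`episode_max_span_days`. The guidance behind these rules gives ranges
("7–10 days", "2–3 days between"); we default to the permissive end —
span 10, gap 3 — and expose both as configuration, because a fixed
mid-range value would silently split episodes that practitioners would
read as one.

Each episode is dated by the first day symptoms appeared, unless a
positive culture from the primary site of infection (blood for
bloodstream, respiratory secretions for pneumonia, wound material for
surgical sites) precedes symptom onset — then the specimen date is the
infection date. Only late-onset episodes count as healthcare-associated:
at least 72 h after birth. When only dates are known this is day of life
4 or later (day of birth = day 1); when a birth time and an onset time
are both available, exact hour arithmetic is used instead. We do not mix
granularities: a date-only onset is never combined with a birth time,
because that would make the boundary depend on which patients happen to
have times recorded.

Classification matches the episode against configured criterion sets, in
precedence order within the body system:

* **LCBSI, recognized pathogen** — a primary-site culture growing a
  recognized pathogen suffices on its own.
* **LCBSI, common commensal** — a commensal culture counts only together
  with clinical *and* laboratory findings (a lone skin-flora isolate is
  treated as probable contamination, and classifies as nothing).
* **Clinical sepsis** — clinical and laboratory findings with no detected
  organism. Laboratory confirmation always outranks clinical sepsis;
  hematogenous meningitis is recorded under the bloodstream criteria
  rather than as a separate type.
* **Pneumonia** — clinical, imaging and laboratory findings all present.
* **NEC** — clinical plus radiological findings, or surgical evidence
  alone.
* **SSI** — a depth-tagged local criterion; the deepest depth present
  wins (organ/space over deep over superficial).

Urinary tract, bone/joint and cardiovascular infections are outside the
surveillance scope (they are rare in this population); their criterion
codes simply do not exist in the vocabulary, so such findings fail
validation loudly rather than silently classifying as nothing.

**Device association.** A bloodstream infection or clinical sepsis is
CVC- or PVC-associated, and a pneumonia INV- or NIV-associated, when the
device accumulated at least three consecutive device-days in a run ending
on the onset day or the day immediately before it. When both devices of a
pair qualify, the association goes to the higher-risk device (CVC over
PVC, INV over NIV); the precedence is configurable.

**SSI attribution.** A surgical-site episode is attributed to the most
recent prior surgery with onset within 30 days of the procedure date
(difference of 0–30 days inclusive), extended to 90 days when an implant
was placed and the depth is deep incisional or organ/space. Superficial
SSIs never use the extension. We read "within 30 days following surgery"
as an inclusive day-difference window; the alternative convention
(procedure day = day 1, window days 1–30) shifts every boundary by one
day and is available by setting `ssi_window_days` to 29/89. An episode
with surgical-site findings but no qualifying surgery is not counted.

**Repeat suppression.** From an infection's date, 14 days must pass —
including at least one symptom-free day — before an infection of the
same organ system is registered again. A later episode inside the window
is merged into the prior infection: its organisms and resistance markers
are appended and it is not counted. We suppress per organ system rather
than per exact type because a new pathogen in the same organ system is
explicitly not a new infection, and the bloodstream types (clinical
sepsis and both LCBSI forms) are one outcome family; suppressing only
exact type matches would double-count a sepsis re-labelled LCBSI by a
late culture. The symptom-free requirement defaults to a single day, the
weakest reading of "a symptom-free period", and is configurable.

**Secondary bloodstream infections** (optional reporting, off by
default): a bloodstream infection is flagged secondary when a pneumonia,
NEC or SSI of the same patient is active at its onset and — when the
primary has documented organisms — shares at least one. The activity
window of the primary is not specified anywhere; we reuse the 14-day
repeat horizon, the only temporal scale the rule set already defines for
"the same infection is still going on". Both the window and the organism
concordance requirement are configurable.

**MDRO.** An infection involves a multidrug-resistant organism when any
of its organisms carries a resistance marker (MRSA, VRE, 3GCR,
carbapenem or colistin resistance). Markers are inputs; the engine does
not interpret susceptibility data.

## Metrics and the standardized infection ratio

Rates are computed per birth-weight stratum (< 500, 500–999, 1000–1499,
≥ 1500 g; half-open bins) and pooled; stratified numerators and
denominators sum exactly to the pooled ones. Any rate with a zero
denominator is reported as missing, never as zero or NaN — a benchmark
must distinguish "no exposure" from "no events". Specific SSI rates are
grouped by the 3-character prefix of the main procedure code by default;
the grouping function is a parameter because no standard grouping list
exists yet for this population.

The SIR compares observed infections to the count expected under
reference rates stratified by birth weight *and* day of life, because
units differ in how many high-risk early days they accumulate. Day-of-life
bands are not prescribed anywhere; the default — 1–3, 4–7, 8–14, 15–28,
29+ days — separates the pre-HAI window (days 1–3 cannot contain
late-onset infections), the first and second weeks, the rest of the
neonatal period, and beyond. Band edges are echoed in every report and
benchmarks refuse to pool units with differing edges: an SIR is only
meaningful across identical stratification. Expected counts are
Σ rate × patient-days over cells; an occupied cell with no reference rate
is an error naming the cell. Expected = 0 with observed > 0 is reported
as incalculable with the observed count, never as infinity. The ≥ 1500 g
stratum contributes to reference data by default (it is part of the
surveillance population), and a unit benchmarked against reference rates
derived solely from itself has SIR 1 in aggregate and in every cell with
events — the self-consistency anchor the test suite asserts.

## The synthetic cohort generator

`simulate_cohort()` draws a complete unit from a single seeded RNG
stream, consumed in a fixed order (patients in sequence; per patient:
demographics, stay layout, exposure runs, daily event/noise draws,
surgeries). It emulates the *structure* of unit data: a birth-weight mix
weighted to the 500–1499 g strata, geometric stays (mean 30 days, minimum
5), devices and antibiotics in multi-day runs with occasional sub-12 h
partial days, daily protective-factor draws, and per-day infection
hazards of a few events per 1,000 patient-days with bloodstream
infections most common — numbers chosen as plausible for a mixed-acuity
neonatal unit. Planted events emit the full criterion set of their type
over 1–3 days, with the primary-site specimen sometimes one day before
symptom onset (exercising the infection-date rule), supporting device
runs ending at onset for a configurable fraction, surgeries with
1–40-day SSI onset offsets (so some fall outside the attribution window
by design), and isolated non-classifiable noise findings.

Planted events of one body system are separated by at least 8 days. This
is a structural guard, not a tuning choice: with a 3-day assembly gap,
symptoms spread over up to 3 days and specimens up to 1 day early, 8 days
is the smallest separation at which two planted events can never fuse
into one episode, so the planted truth remains a well-defined expectation
for the classifier. Events closer than 14 days still occur freely and
exercise repeat suppression.

What the generator does *not* emulate: correlated risk (device use and
infection hazard are independent), transmission between patients,
seasonal or secular trends, missing or contradictory data entry, and
realistic clinical trajectories. Passing recovery tests therefore shows
that the engine applies the rules exactly as specified — not that the
rules themselves are sensitive or specific on real records.

## Validation strategy and problem sizes

The test suite checks, at sizes chosen to keep the full run in a few
minutes on one core:

* every threshold one unit below, at, and above its boundary;
* episode assembly, device association and repeat suppression against
  brute-force re-implementations on 1,200 randomized instances;
* exact recovery of the rule-aware planted truth on 100 cohorts of 50
  patients each;
* incidence density within three binomial standard errors of
  1000 × hazard on a simulated unit of > 50,000 patient-days
  (λ = 0.002/day), and SIR within 3/√expected of 1.0 when a cohort
  simulated under known cell rates is benchmarked against those same
  rates (hazards placed in the late-onset bands so the late-onset filter
  does not bias the count; residual bias from the 14-day rule and event
  separation is on the order of 1–2 %);
* conservation: stratified days and counts always sum to pooled totals.

## Known limitations

* Date-granular rules are conventions (48-h gaps, 72-h onset, SSI
  windows); units recording times can sharpen only the late-onset rule.
* The bundled criterion vocabulary and organism catalog are compact
  defaults; real deployments should extend both configuration files.
* No statistical inference on rates or SIRs (no confidence intervals or
  significance tests) — the engine reports point quantities.
* Antimicrobial use is counted in days, not defined daily doses.
* One surveillance episode per patient: re-admissions after a > 48 h
  absence are flagged and excluded rather than modelled.
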