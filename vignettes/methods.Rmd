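---
title: "Methods: dual-source EMR verification, respiratory phenotyping and rate estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-source EMR verification, respiratory phenotyping and rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrcohort)
library(data.table)
```

## The problem this package addresses

Before an electronic-medical-record (EMR) platform can support
longitudinal respiratory research or pragmatic trials, two questions must
be answered. First, *can the extraction be trusted*: when the same GP
records are pulled through two independent routes, do the two extracts
agree at the patient and record level? Second, *is the content rich
enough*: can asthma and COPD cohorts be phenotyped from coded data, and
can clinically meaningful outcome rates — exacerbations and health-care
resource utilisation (HRU) — be computed over person-time?

The package implements both halves as a tested pipeline. Because GP data
cannot be shipped, a synthetic-data module generates a ground-truth
primary-care population and derives two independently corrupted source
extracts from it, so that every downstream stage can be verified against
a known truth.

## The synthetic registry

`generator_params()` fixes the study conditions; `generate_population()`
simulates them. Each adult receives a sex, an age (truncated normal,
mean 49, SD 18, range 18–95, stated as of 2008-12-31), coded diagnoses,
prescriptions, GP visits, hospitalisations, and possibly a death or a
deregistration (competing exponential hazards, 0.01 and 0.02 per year).
No journal record is ever dated after the patient's exit.

Defaults were chosen once, from the magnitudes a large UK primary-care
registry reports for these quantities, and are not tuned thereafter:

* **Disease labels.** Coded asthma in 4.4% of adults without COPD; coded
  COPD in 4.1% of adults aged 40 or over (about 2.5% of all adults once
  the age distribution is applied); 38% of COPD patients carry a
  comorbid asthma code.
* **Prescribing.** Per-class probabilities per disease group (e.g.
  ICS/LABA combination 0.40 for asthma, 0.55 for COPD; LAMA 0.36 for
  COPD), with roughly eight repeat scripts per prescribed class per
  year, 28 days' supply each. A small fraction (2% asthma, 5% COPD)
  receives maintenance oral corticosteroids as monthly 28-day scripts —
  these exercise both the severe-asthma exclusion and the short-course
  distinction below.
* **Exacerbations.** A two-class Poisson mixture rather than a negative
  binomial: a *frequent* class (default 6% of diseased patients) with
  1.4 treated events per person-year and an *infrequent* class with 0.2.
  The two-class form directly supports the ≤1 / ≥2 baseline
  stratification that the feasibility question turns on; a continuous
  frailty would blur the class boundary without adding anything the
  tests could check. Each event produces an OCS course of 5–7 days'
  supply for asthma (OCS and/or antibiotics for COPD), and 5% of events
  are severe, adding a respiratory admission with a log-normal length of
  stay.
* **Background utilisation.** GP visits at 10.7 per person-year for all
  adults; all-cause admissions at 0.30 per person-year of which 0.03 are
  respiratory.
* **Measurements.** FEV1 and FEV1 %predicted for ~80% of diseased
  patients (normal around 2.42 L / 86% for asthma, 1.45 L / 61% for
  COPD), smoking status, BMI, and peak expiratory flow for asthma.

Corruption (`corruption_profile()`, `corrupt_to_source()`) emulates what
an extraction route does to the truth: whole patients silently missing,
records dropped by kind, records duplicated, and re-keying under
source-specific pseudonyms. The pseudonym→person map is retained on the
object purely as a test oracle and is never written to disk.

**What the generator does not emulate.** Age–disease and
deprivation–disease correlation, seasonality of exacerbations,
free-text, miscoding (a wrong code rather than a missing record),
non-exacerbation antibiotic prescribing, and within-patient rate
autocorrelation beyond the two-class mixture. Passing tests therefore
demonstrate that the *algorithms* are correct under known conditions,
not that real Salford-like data would be this well behaved.

## Dual verification

`match_patients()` is deliberately deterministic, not probabilistic
(no Fellegi–Sunter weights): stage 1 matches literally identical
pseudonym keys (the NHS-number-linkage situation); stage 2 matches the
remainder on an exact fingerprint of age, sex and the three earliest
distinct journal dates. A fingerprint shared by two or more patients on
either side is ambiguous and those patients are left unmatched — a
deliberate precision-over-recall choice, since a wrong link corrupts
every downstream comparison while a missed link only shrinks it.

`merge_prescriptions()` pools the matched patients' prescription
records, collapsing records equal on (patient, code, date, quantity),
and counts the records unique to either source. The same merge applied
to diagnosis-concept events yields the missing-record counts.
`compare_condition()` cross-classifies matched patients by the presence
of a diagnosis concept in each source, and `cohen_kappa()` computes

$$\kappa = \frac{p_o - p_e}{1 - p_e}$$

from the 2×2 margins. On a degenerate all-one-class table (expected
agreement 1) kappa is reported as 1 with a `degenerate` flag rather than
an error, so the identical-extracts case stays usable in reports.
`verification_report()` stores all percentages unrounded; printed
precision is a formatting concern of the caller.

## Phenotyping

`build_cohort()` applies the eligibility rules in a fixed order, logging
every exclusion with the rule that fired and keeping flow counts:

1. a coded asthma (or COPD) diagnosis during or before 2008;
2. at least two prescriptions for inhaled bronchodilators between
   October 2007 and December 2008 (evidence of current disease
   activity). Combination ICS/LABA inhalers count toward this — they
   contain a long-acting bronchodilator — which is an interpretation:
   the criterion could be read as bronchodilator-only inhalers;
3. age ≥ 18 (asthma) or ≥ 40 (COPD) at 2008-12-31. The reference date
   is a design choice; the age thresholds come with no stated reference;
4. no cystic fibrosis, lung cancer, bronchiectasis or fibrotic lung
   disease coded in 2008–2009;
5. asthma only: no severe asthma, operationalised as more than 90
   days' supply of OCS during 2008 where overlapping scripts are capped
   at calendar coverage (a supply criterion, not a script count), and no
   COPD co-diagnosis at any time. The COPD cohort permits comorbid
   asthma and flags it.

All windows are half-open `[start, end)`, which keeps date arithmetic
unambiguous (a full default follow-up year is exactly 365 days).

Baseline characterisation uses the *first* lung-function measurement
recorded in 2008, ties broken by lowest record id (deterministic); the
*latest* smoking and BMI record up to the end of 2008; GOLD stages at
the conventional 80/50/30 %predicted cut-offs (the stage distribution is
reported without cut-offs wherever it is published, so the convention is
a design decision); and cardiovascular comorbidity codes dated before 31
December 2009. Medication classes follow the reporting convention in
which ICS users partition into ICS+LABA (combination product *or*
co-prescription of separate inhalers in the year), else ICS with LTRA or
LAMA, else ICS monotherapy.

## Outcomes

`identify_exacerbations()` turns trigger records — short-course OCS
and respiratory admissions for asthma, plus antibiotic courses for COPD
— into episodes: a record starting within `merge_window_days` (default
14) of the running episode's end joins it; admissions extend the end to
their discharge date; an episode containing any respiratory admission is
severe. Two numerical choices deserve note:

* **14-day merge window.** The event-level definition comes with no
  grouping rule; 14 days is the prevailing pharmacoepidemiology
  convention for separating treated exacerbation episodes. Setting it
  to 0 makes episodes equal distinct trigger dates; infinity collapses
  each patient to at most one episode — both degenerate cases are tested.
* **Short course = supply ≤ 21 days.** Without this, a patient on
  maintenance OCS would register an "exacerbation" every 28 days.
  Scripts with no recorded supply count as short courses.

`person_time()` censors at the earliest of death, deregistration and the
administrative end of 2009, with a 365.25-day year. The boundary is
exclusive: death on 2 July 2009 contributes 182/365.25 person-years, an
uncensored patient 365/365.25.

`hru_rates()` counts OCS short courses, antibiotic scripts, GP visits
(deduplicated to one per patient-day, an interpretation since same-day
double contacts are ambiguous in coded data), and all-cause and
respiratory admissions within each member's follow-up, per stratum, as
rates per 100 person-years. Patients with more than 12 OCS scripts in
2008 are excluded from the OCS row — numerator *and* denominator — as
outliers; consequently the OCS row's person-years may differ from the
other rows', which is the arithmetically forced consequence of excluding
patients from one outcome only. Baseline (2008) exacerbations for the
≤1 / ≥2 stratification use the same episode algorithm applied to 2008.
An empty stratum yields a flagged zero-person-years row, never a
division by zero.

## Alerts

`alert_engine()` retains, between daily batches, the set of ingested
records and the set of emitted alerts keyed by (rule, patient, trigger
set). `ingest_batch()` rejects records dated after the batch date,
evaluates value-threshold and count-in-sliding-window predicates over
retained state, and is idempotent under batch replay. Alerts are
append-only; retraction of corrected records is out of scope. The
shipped rules are illustrative only — no concrete production criteria
are published for the mechanism this emulates.

## Problem sizes and verification strategy

The test suite verifies each operation against an independent oracle at
small scale: brute-force pairwise merging on ≤ 200 records, an
exhaustive 64-patient truth table covering every combination of the six
eligibility predicates, hand-simulated episode merging, interval-sum
oracles for hospital days, and closed-form binomial/Poisson 99%
intervals for every stochastic generator rate. The statistical
rate-recovery check runs the full pipeline on ~4,600 patients per
replicate (≥ 2,000 per exacerbator class) with rates 1.4 and 0.4 per
person-year and confirms the estimated rates bracket 140 and 40 per 100
person-years inside the Poisson 99% interval, with the
frequent-over-infrequent ordering holding in every replicate. The
`analysis/` scripts run the same pipeline narratively on a 3,504-adult
registry. These sizes were chosen to make the oracle intervals tight
enough to be informative while keeping the whole suite comfortably
quick to run.

## Known limitations

* Matching quality degrades with event-record corruption, because the
  demographic fingerprint is built from journal dates; the shipped demo
  shows ~97% patient recall under a 1% event-drop rate. Real platforms
  would link on a stable identifier (stage 1).
* A single exacerbation-rate mixture is shared by asthma and COPD; the
  published COPD rates are higher than the asthma ones, which a
  per-disease mixture would capture.
* Non-exacerbation antibiotic prescribing is not generated, so the
  synthetic COPD exacerbation counts are cleaner than real coded data,
  where an antibiotic script may reflect any infection.
* The code list is a 60-code stand-in; nothing in the logic depends on
  real Read codes, but code-level idiosyncrasies (synonym codes,
  miscoding) are untested by construction.
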