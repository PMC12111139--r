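---
title: "Assessing ADHD drug adherence from dispensing claims: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing ADHD drug adherence from dispensing claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhere)
```

This vignette is the package's own account of the adherence methodology it
implements: the model and its assumptions, the tunable parameters, what
the synthetic-data generator does and does not emulate, the numerical
choices made where the underlying method statement was open, and the known
limitations.

## The problem

Pharmacy claims record dispensings, not ingestion. For adult ADHD
pharmacotherapy this gap is especially awkward: stimulant therapy may be
interrupted deliberately (drug holidays), monthly prescription renewal
rules make refill friction drug-specific, and comorbid depression brings
concurrent antidepressant therapy whose continuous-dosing convention
differs from the stimulant's. The pipeline therefore measures adherence
two complementary ways — a coarse monthly-issuance consistency criterion
(the treatment-adherent group, TAG) and a day-resolution Proportion of
Days Covered (PDC) — and keeps methylphenidate and antidepressant streams
separate throughout.

## Cohort construction

Patients enter if aged between 18 and 40 with a "CNS other" class drug
(methylphenidate, atomoxetine, flumazenil) dispensed during the 2015 index
year, followed over 2012–2016. Three gates run in a fixed order so every
exclusion is attributable to exactly one of them:

1. **Age**: at least 18.0 years on 2012-01-01 *and* between 18 and 40 at
   some point of the index year. Operationalising the age rule this way
   reproduces the removal of patients who were 17 during the first study
   year while honouring the 18–40 selection.
2. **Index claim**: at least one index-class dispensing dated in 2015.
3. **Flumazenil-only**: patients whose index-class claims are exclusively
   flumazenil and who carry no F90 code received no ADHD-indicated drug
   and leave the cohort.

Diagnostic grouping matches the ICD-10 prefix `F90` case-insensitively on
any claim in any study year. Any-year matching is a deliberate choice: a
diagnosis code observed only after the index year still evidences a
confirmed diagnosis over the study period. Grouping is code-driven only;
no attempt is made to infer a diagnosis from drug patterns.

**Tricyclic filter.** Low-dose tricyclics are commonly dispensed for
indications other than depression (pain, insomnia). A tricyclic claim is
excluded from the antidepressant analyses when its implied daily dose is
below the agent's accepted minimum antidepressant dose, its implied
coverage is below 14 days, or it carries diagnostic codes none of which is
a mood-disorder code (prefixes F32, F33, F34, F38, F39, F41 by default).
The dose thresholds live in the formulary, not in code, because they are
agent-specific clinical facts; excluded claims are retained for audit.

## Monthly plotting and the TAG

Dispensings are consolidated onto a 60-month grid per patient and drug
type (stimulants: methylphenidate and atomoxetine; antidepressants after
the tricyclic filter). When two same-type dispensings fall in one calendar
month, two reassignment rules may move one of them a single month — the
plotted month only, never the record:

* **Rule 1** applies when the refill gap is at least 21 days, an adjacent
  month holds no issue, and the moving claim matches the locally stable
  pattern. "Stable pattern" is operationalised as the modal
  (drug code, strength, quantity) combination within a ±3-month window,
  and the claim nearer the empty month is the one that moves.
* **Rule 2** applies when the local trend is regular: if total units over
  total days across the window match the estimated daily dose within
  ±20%, the later claim is an early refill and is attributed to the
  following month. The 20% tolerance is a design choice — the underlying
  rule statement gives none — and rule 2 only fires when the receiving
  month is empty, which prevents reassignment cascades. Rules are applied
  iteratively until the grid is stable; application to an already
  consolidated grid changes nothing, and each claim moves at most once.

**Daily dose estimation.** Where at least two stable refill gaps in the
7–45-day range exist, the units-per-day rate is the median quantity/gap
ratio snapped to the nearest of {0.5, 1, 1.5, 2, 3}; ratios outside 1.5×
that range are treated as no evidence. Otherwise one unit per day is
assumed. Supply days per claim are `floor(quantity / rate)`, floored at
one day. The days-supply field present on some claims is deliberately
ignored even where available, for consistency of method across years.
Claims covering fewer than 14 days are flagged short-supply and never
count as a month of medicine coverage.

**TAG.** A patient is treatment-adherent when they accumulated at least 12
issue months of either drug type over the five years *and* at least 7
issue months within some rolling 12-month window (49 windows). The two
criteria are combined conjunctively by default because they are stated as
one joint classification; an `OR` policy switch is provided since the
conjunction is a reading, not a statement. Months are counted jointly
across drug types — a month with both a stimulant and an antidepressant
issue counts once.

## PDC under issue-anchored periods

Coverage is the union of half-open day intervals `[issue, issue + supply)`.
Assessment periods open at an issue date — not on calendar quarters —
because prescriber-intended durations are unobservable and every worked
refill pattern anchors on a first issue. Day counting is the
start-exclusive difference `end − start` throughout.

Each period nominally runs 90 days, adjusted by what the dispensing dates
show, with specific rules taking precedence over general ones:

| rule | condition | period end |
|---|---|---|
| `less_90` | a month inside the period holds no issue, and an issue 75–89 days in opens a follow-on period with ≥ 60 covered days in its first 91 days | that issue date |
| `120_129` | next issue falls 120–129 days out under a regular (≤ 45-day gap) cadence | next issue date |
| `over_90` | next issue falls 91–119 days out | next issue date |
| `up_to_119` | no such issue, but cover runs past day 90 | end of cover, capped at day 119 |
| `standard` | otherwise | day 90 |
| `db_end` | any period reaching past 2017-01-01 | truncated there (terminal; may be < 90 days) |

The 75-day floor operationalises "slightly before the nominal end"; the
worked shortened period closes at 82 days. A refill break long enough that
the next issue is beyond every extension band (more than 119 days out, or
120–129 under an irregular cadence) opens a new period at that issue:
periods are contiguous within refill runs but deliberately do not bridge
long treatment breaks, which keeps drug holidays from being scored as
non-adherence and keeps every period within the 1–129-day range.

Per-period PDC is covered days over duration. By default coverage is
clipped only at the database end, not at the period end, so a period
closed early by a dense refill pattern can exceed 1 — possession-based
measures are known to inflate this way, and averaging across periods is
the intended mitigation. A `cap_pdc` switch clips coverage to the period
for strict [0, 1] semantics. A patient's adherence per drug type is the
unweighted mean of period PDCs (weighting by duration is an alternative
reading; unweighted was chosen and recorded). Patients with no periods
are missing, never zero.

**PDD.** The prescribed daily dose is total dispensed milligrams over
days of cover, compared against a configurable 30 mg methylphenidate DDD.
Note the denominator is *covered* days: overlapping early refills shrink
it, so measured PDD can sit slightly above the prescribed rate in noisy
streams — visible in the synthetic recovery checks, where the noiseless
generator recovers 30 mg/day and the jittered one runs ~1 mg higher.

## Inference

Fisher's exact test is implemented by direct hypergeometric enumeration
over the table support at fixed margins, with the two-sided p-value
defined by the probability-mass method (sum of table probabilities not
exceeding the observed one, with a 1e-7 relative tie tolerance). A zero
margin returns p = 1 by convention. PDC is dichotomised at the 0.80
adherence convention (inclusive), configurable. The TAG logistic model
uses `stats::glm` with per-coefficient Wald chi-squares and a type-3
likelihood-ratio test per variable (full model versus the model dropping
the variable's whole term block, invariant to term order). Age is banded
at the index-year midpoint into 20–24 / 25–29 / 30–34 / 35–39 with the
youngest band as reference; separation is flagged in the result status
rather than raised as an error, since co-therapy can perfectly predict
TAG in small or synthetic cohorts. No multiple-testing correction is
applied, matching the analysis design this implements.

## The synthetic generator

`generate_cohort()` emulates the structure the analysis assumes: five
years of monthly claims, an F90/non-F90 mix of 0.56/0.44, antidepressant
co-therapy probabilities of 0.40 (F90) and 0.33 (non-F90), uniform ±3-day
refill jitter, ICD-10 codes absent in 2012–2013, methylphenidate as
90 × 10 mg units monthly at three units per day (30 mg/day) for sustained
users, and five usage archetypes (regular, irregular, holiday — June and
December breaks — discontinuer, antidepressant-dominant). Decoy patients
(under-age in 2012, flumazenil-only, sub-therapeutic tricyclic) exercise
the gates. Per-patient RNG substreams are keyed on the patient index, so
extending a cohort never perturbs earlier patients, and identical
(spec, seed) pairs are byte-identical.

Ground-truth labels carry each patient's archetype, group, eligibility
status and TAG intent (the TAG rule applied to the intended issue-month
schedule). What passing label-recovery tests show is that the pipeline
inverts *this* generative structure — clean monthly cadences, stamped
codes, known decoys — at 100% without jitter and ≥ 95% with it. Real
claims have messier features the generator deliberately omits: strength
switches and titration, pack-size variety, claim reversals, privately
paid fills missing from claims, concurrent prescribers, and partially
coded diagnosis fields beyond the simple missing-years pattern. Passing
tests on synthetic data therefore validate the machinery, not the
real-world error rate.

## Problem sizes and numerical notes

The shipped checks use sizes chosen to make the properties sharp but the
suite quick: 1,000 random streams (≤ 500-day windows) against a
brute-force day-enumeration coverage oracle; all 135,751 2×2 tables with
N ≤ 40 against independent binomial-coefficient enumeration (agreement to
1e-12); odds-ratio recovery at n = 2,000; label recovery on a 500-patient
cohort. Ties in the modal-pattern computation break toward the most
frequent, first-seen combination; dose snapping breaks ties toward the
lower rate; dates are ISO-8601 and all month arithmetic uses the study
grid index. Degenerate inputs are mapped to explicit values: empty
streams segment to nothing, zero covered days yield missing PDD, empty
report cells render blank rather than 0.0.

## Limitations

Beyond the generator's simplifications above: the assessment-period rules
are a faithful but necessarily interpretive encoding of a rule table with
one internally inconsistent worked date (a fifth issue printed with a
year that contradicts its own stream; the implementation follows the
stated 82-day total and treats that issue as opening the next period,
consistent with the quoted 91-day/60-covered follow-on). Dispensing-based
measures cannot observe ingestion; no hospitalisation, switching or
stockpile carry-over beyond explicit supply intervals is modelled; and
atomoxetine is carried through the stimulant stream even though real
cohorts may hold too few users to analyse it separately.
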