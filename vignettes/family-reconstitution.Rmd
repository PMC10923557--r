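---
title: "From parish registers to marital fertility rates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From parish registers to marital fertility rates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reconkit)
```

# The problem

Family reconstitution links baptism, marriage and burial entries from a
parish register into family histories: a marriage, the two spouses, their
children, and (where the register allows) the spouses' parents and later
marriages. The resulting histories support demographic measurement in the
centuries before censuses — but only if families are selected with care.
Parish registers practice *passive registration*: a family's presence in
the parish is known only on the days an event was recorded, and migration
is never observed directly. Ending a fertility history at the last
observed child event therefore censors informatively — women with shorter
birth intervals have shorter gaps between their last birth and their
unobserved departure — and inflates estimated fertility. The classical
rules of family reconstitution (Henry's rules) avoid this by ending an
observation window only at an event independent of the children: the
death of a spouse, or the wife's 50th birthday.

`reconkit` implements the full data pipeline around this measurement
problem: parsing the digitised Family Reconstitution Form (FRF) text
format, conversion to a relational table bundle and then to the five-table
Intermediate Data Structure (IDS), chronicle and episode construction for
event-history analysis, rule-based family selection, and weighted
age-specific marital fertility rates (ASMFR) with the total marital
fertility rate TMFR = 5 × Σ ASMFR over ages 20–49. A synthetic
parish-register simulator with known ground truth makes every stage
testable and demonstrates the censoring bias quantitatively.

# Pipeline stages and their contracts

## FRF text format

Each record is a group of `/`-separated lines terminated by `$`: `M`
(marriage, first line, carrying the FRF number), `H`/`W` (spouses), `C`
(children, repeatable, in birth order), `HM`/`HF`/`WM`/`WF` (parents),
`L` (literacy), and `F` (flag lines of repeating target/code pairs, e.g.
`F/H/W/C1/Z2/C2/Z2`: husband widowed, children 1 and 2 stillborn twins).
Dates may be paired — baptism with birth, burial with death, the second
in brackets — and may carry an asterisk-prefixed *weighting*, a numeric
precision code (not a statistical weight). Missing values are `-`.
Because the archived per-parish layouts differed slightly, the per-line
variable positions are a configurable layout
(`default_frf_layout()`) rather than a hard-coded schema, and whitespace
around separators is tolerated. Serialization is an exact token-level
inverse of parsing; the round trip is checked on every synthetic register.

## Date normalization and the weighting arithmetic

Day or month parts recorded as 0 become 1, with the weighting augmented by
1000 (day ambiguity) and/or 2000 (month ambiguity) on top of the at most
3-digit base code, so the change is reversible. An impossible 29 February
becomes 28 February with +3000 when the date was invalid in the Julian
calendar too (year not divisible by 4) and +4000 when it was Julian-valid.
All normalized dates are proleptic Gregorian; Julian arithmetic is used
only for this classification, and no Julian-to-Gregorian or Lady-Day
year-start conversion is attempted — archived dates are taken as already
normalized. A bare weighting of base + 3000 is ambiguous between
{day, month} ambiguity and the Julian-invalid leap fix; the attached date
disambiguates it deterministically (`decode_weighting()`), because a leap
fix always leaves 28 February of a non-leap year while the ambiguity
offsets force the adjusted part to 1.

## IDS conversion

Each family becomes a `Union` context timestamped at the marriage; every
member is linked to it, and kinship is recorded in mirrored
`INDIV_INDIV` pairs. Individual IDs append a role suffix to the family
key (`W`, `H`, `C01`…, `WF`, `WM`, `HF`, `HM`); child numbers are
zero-padded to two digits so IDs sort. Weightings map to IDS
`Estimation` labels: no weighting means the source gave day, month and
year (`Exact`); day ambiguity gives `Estimated (dd)`; month ambiguity
`Estimated (dd/mm)`; base codes meaning a bound (a spouse death proxied
by the survivor's remarriage, a father's death inferred from a posthumous
birth) give `Before this date`. Unknown base codes map to a conservative
`Estimated` with a warning rather than `Exact`. A child with a burial but
no baptism or birth gets a *dummy birth* record (estimation
`"Dummy birth (burial date)"`), dated at the death date when the burial
token carried one and at the burial otherwise — the death date, when
known, is the sharper lower bound and keeps within-person event ordering
consistent. The original widowhood flags are deliberately not imported:
their provenance is unreliable, so widowhood is inferred from burial
dates only.

Cross-family links (a child's own first marriage; a spouse's earlier or
later marriage) define equivalence classes of IDs, resolved by union-find;
each class is rewritten to the ID whose earliest dated event comes first,
with lexicographic tie-breaking for determinism. Cyclic marriage-order
links — chronologically impossible — are reported, not silently repaired.

## Chronicle and episodes

The chronicle lists dated attribute changes per married woman: marital
status, parity, a lactation indicator, and an indicator that the
previously born child has died. Baptisms of one union within 60 days are
collapsed to a single birth event (twins were often baptized days or
weeks apart), and the rate denominator treats a multiple birth as one
event; rates can be inflated afterwards by an explicit multiple-birth
share (`inflate_for_multiplicity()`, about 1.5%, off by default). The
lactation indicator opens at each birth and closes at the earlier of the
newborn's death and a weaning horizon of 24 months — the indicator is
standard in this literature but its horizon is not; 24 months is a
conventional maximal breastfeeding span for the period, and it is a
configurable argument, not a constant.

Episodes are half-open `[start, end)` segments with constant covariates,
split at every covariate change, every crossing of a 5-year age bound,
and every calendar-period bound (default 25-year bands; band width is
configurable since period reporting conventions vary). Age is exact
days/365.25 from the birth-proxy date (baptism when birth is absent); the
boundary day for age *a* is the first day with age ≥ *a*, which makes
episode splitting agree with a day-by-day enumeration oracle to within
rounding. An episode ending on a birth event date carries `event = 1`; a
birth on the day observation closes still counts, because passive
registration proves presence at the event. Per woman, episode durations
sum exactly (to the day) to her window length.

## Selection criteria

`criteria_set()` reconstructs the reference selection rules as an
auditable conjunction of individually toggleable clauses:

* **Pre-requisites** — a wife birth/baptism date and a marriage date
  (proxies allowed: baptism for birth, burial for death).
* **Henry window** — an observed spouse death is required; entry is
  max(marriage, wife's 15th birthday), exit min(first spouse death,
  wife's 50th birthday). Variants: `ends_age_50` (first spouse death
  after the wife turned 50), `spouse_died_lt50` (its complement),
  `two_spouse_deaths` (both deaths dated), and the diagnostic
  `violating_child_end` whose windows end at the last child birth or
  under-15 child death — the informative-censoring violation, disjoint
  from the reference sample by construction.
* **Date precision** — families are excluded when the month of marriage,
  wife's birth or the window-ending spouse death is estimated
  (`Estimated (dd/mm)` or worse, including `Before this date` remarriage
  proxies); children's birth months must be known. Dummy births are
  *included* in the reference set (toggle `allow_dummy_births`): burial
  dates are day-precise, and excluding families with an unbaptized dead
  child would select against high-fertility families.
* **Marriage order** — reference keeps first marriages for both spouses,
  inferred from links and dates only, never from the widowhood flags.
* **Parish and period** — windows must begin and end inside the parish's
  quality years and sample-group years; Birstall is excluded from
  fertility (no childless-family records, so its inclusion would inflate
  rates) and Shepshed is half-weighted; all other parishes weigh 1.
* **Occupation** — optionally require a recorded husband occupation.

Each decision carries its ordered exclusion reasons, and a funnel report
gives families and person-years surviving each stage; monotonicity of the
funnel is a tested invariant. Decisions are independent of input order.

## Rates

`person_years_and_births()` accumulates weighted person-years and events
per (age group × period) cell; cells with zero exposure have an undefined
rate, never 0. An episode's period is its start date's band, which is
exact because episodes never straddle period bounds. Weighted aggregation
is linear, so per-parish tables sum to the pooled table.

# The synthetic parish simulator

The simulator is first-class, tested code that defines the study
conditions, not a fixture. It emulates the statistical structure the
analysis assumes; each default is either conventional in the
natural-fertility literature or documented here as plausible-but-arbitrary:

* Marriage formation over a 1580–1837 register window; wife age at
  marriage normal(24, 5) truncated to 15–45.
* Monthly fecundability 0.12 up to age 24, declining linearly to 0 at
  age 47 — natural-fertility populations show small but positive rates
  at 45–49; 9 months gestation; a 12-month postpartum non-susceptible
  period, shortened to 2 months after the nursling dies.
* Stillbirth probability 0.02 per baby; twin probability 0.015 per birth
  (matching the conventional multiple-birth share); infant death
  probability 0.15; a further 0.08 probability of death at ages 1–15
  (childhood mortality, which also supplies the under-15 child deaths
  the Henry rules are about).
* Adult mortality hazard 0.02/year from marriage; couple out-migration
  hazard 0.05/year. Migration truncates *registration*, never the
  demographic process: the complete event log continues and is the
  ground truth.
* Baptism delay Poisson(7 days) with a 5% chance of an extra 30–90 days
  (so 60-day collapsing is exercised); burials 2 days after death; each
  event independently unrecorded with probability 0.03.
* Widowed spouses remarry in the parish with probability 0.3, creating
  earlier/later-marriage links; surviving daughters marry in the parish
  with probability 0.25, creating own-first-marriage links. A family
  that migrated before such a marriage contributes no in-parish record
  of it.
* Date-precision noise: 3% of marriages and wife baptisms recorded to
  the year only, 5% of marriages to the month; an unregistered spouse
  burial followed by an in-parish remarriage is proxied by the
  remarriage date with the "before this date" weighting — reproducing
  the mechanisms the precision filters exist for.

A single integer seed governs all randomness through one generator
stream, so a fixed seed reproduces the register byte for byte.

What the generator does *not* emulate: secular trends and seasonality in
fertility or mortality, age-dependent adult mortality, social
stratification of fertility (occupation presence is random), real place
names, name-based record-linkage ambiguity, and register gaps. Passing
tests therefore show that the pipeline measures correctly *given* correct
linkage under the stated statistical structure; they do not validate
linkage itself, and parameter defaults make no claim to reproduce any
historical series numerically.

# What the experiments show

Two replicated experiments define the package's empirical claims; both
are computed by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`, never stated as constants:

* **Parameter recovery.** With migration and under-registration switched
  off, reference-criteria ASMFRs agree with the ground-truth rates
  within Monte-Carlo error (|z| < 3 per age group) at 2,000 couples and
  20 replicates. Censoring by spouse death or the register window is
  non-informative here because mortality and fertility are independent
  by construction.
* **Henry-rule bias.** With migration at 0.05/year, windows ended at the
  last child event give a TMFR above truth in essentially every
  replicate, with the absolute age-specific bias growing monotonically
  from ages 20–24 to 45–49 — the oldest ages have the longest gap
  between last birth and unobserved departure, and every violating
  window ends with an event.

Problem sizes (2,000 couples, 20 replicates; 500 couples for the
day-enumeration audit) give Monte-Carlo standard errors a few per mill
wide on rates around 0.2–0.4, small enough to resolve the biases of
interest while keeping the full suite comfortably fast.

# Numerical choices and degenerate inputs

* Dates are integer days (base `Date`); durations in years are
  days/365.25 throughout, and age-group boundary days are
  `birth + ceiling(a * 365.25)`.
* Zero-length windows and zero-length episode segments are dropped, not
  errors; a window with entry after exit is an error.
* Same-day conflicts in the chronicle resolve by the fixed order birth <
  marriage < death; duplicate same-day birth events for one woman are an
  error (they indicate uncollapsed multiple births).
* Empty rate cells are `NA`; `tmfr()` refuses to extrapolate across an
  age group with no exposure and returns `NA` with a message.
* Unknown flag and weighting codes pass through verbatim and are
  reported — several original code meanings are lost, and rejecting them
  would destroy information. The shipped lookup tables cover only the
  documented subset and mark speculative rows.

# Known limitations

* The per-line FRF variable layout is configurable but the shipped
  default is one plausible layout, not a reconstruction of any specific
  parish's file; archives using other layouts need a custom
  `default_frf_layout()`-style map.
* Remarriage detection sees only in-parish links: a remarriage to an
  in-migrating widow(er) with no earlier record is invisible, as in the
  source data.
* Quality-year and sample-group intervals for real parishes live in
  archive lookup tables; the package ships a schema and synthetic
  metadata and accepts real intervals through `parish_metadata()`.
* The episode file carries the covariates named here; archive episode
  files include further variables that are out of scope.
* Hazard-model fitting (e.g. Cox regression on the episodes) is out of
  scope; the episode CSV is designed to feed standard survival tooling.
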