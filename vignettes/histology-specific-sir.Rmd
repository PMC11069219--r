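---
title: "Histology-specific SIR for same-site second primaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histology-specific SIR for same-site second primaries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirhist)
```

## The estimation problem

A standardized incidence ratio compares a cohort's observed event count
`O` with the count `E` expected if the cohort experienced the reference
population's incidence, `E = Σ_s PY_s · IR_s` over strata `s` (here sex ×
5-year age band × calendar period × region). For *same-site* second
primaries this comparison is broken wherever the registry follows the
IARC/IACR multiple-primary rules: a later lung tumor is registered only
when its histology *group* differs from every previously counted lung
tumor of that patient (and a tumor of unspecified histology matches any
group, in both directions). The observed count is therefore thinned by the
histology mix, while general reference rates are not.

`sirhist` estimates four SIR variants:

* `sir1_raw` — the conventional estimator: all registered second primaries
  against general reference rates.
* `sir2_sub` — the histology-specific estimator: estimation is stratified
  by the index tumor's group `j`; second primaries of group `j` are not
  counted as observed; and the reference rates used for that stratum
  exclude group `j` from their numerator (rates `IR_ij`). Per-cell and
  pooled results are reported; totals always pool `O` and `E` before
  dividing, never average ratios.
* `sir3_iarc` / `sir4_subiarc` — the same two estimators with observed
  events and rate numerators restricted to records that satisfy the
  IARC/IACR rules (the INTPRIM annotation). On data where no same-group
  second primary exists and every record is an international primary the
  four variants coincide pairwise, which the test suite checks exactly.

All confidence intervals are exact Poisson intervals,
`low = χ²_{α/2, 2O} / 2E` (0 when `O = 0`) and
`high = χ²_{1−α/2, 2(O+1)} / 2E`, at a default level of 95%.

### Why the conventional estimator is biased, in closed form

If second-tumor histology follows the index distribution `p` over groups,
only the fraction `x_j = 1 − p_j` of second primaries after an index tumor
of group `j` is registrable. Scaling each expected-count stratum
accordingly yields the ratio an IARC/IACR registry would report:

`SIR_sim = SIR_real × Σ_j w_j x_j`,

with `w_j` the expected-count share of group `j` (`w = p` by default,
i.e. person-time share proportional to group prevalence; `w` is injectable
for other weightings). `simulate_sir_iarc()` evaluates this closed form and
attaches a Poisson CI built from the implied observed count
`O_sim = SIR_real · Σ_j E_j x_j`, rounded to the nearest integer for the CI
only. This CI construction is a convention of this package, stated as such.
Under `unspecified_mode = "block"` the wildcard group's factor is set to 0
instead of `1 − p`: after an index tumor of unspecified histology *no*
second primary is registrable at all.

## Histology grouping

Morphology codes (ICD-O-3, four digits; the behavior digit is ignored for
grouping) are mapped through an editable packaged range table to two
schemes: eight lung groups in the resolution the IARC/IACR rules operate on
(`iarc8`), and the WHO five-group reporting aggregation (`who5`: SCC, AC,
SCLC, LCC, O&U).

Two structural choices were genuinely open and are worth recording. First,
the package's eight groups split small-cell (8041–8045) and large-cell
(8012–8014) carcinoma out as their own groups and merge the unspecified
carcinoma and unspecified cancer ranges into a single wildcard group. The
published 2004 grouping instead files small-cell under "other specific
carcinomas" and large-cell under "unspecified carcinomas"; with that
layout, however, the WHO five-group scheme is *not* a coarsening of the
eight groups, and the package's contract — `who5 = iarc8_to_who5(iarc8)`
everywhere, enforced by a property test — would be impossible. The split
preserves both the group count and the MP-rule semantics (a wildcard group
matching everything) while making the aggregation exact. Second,
bronchiolo-alveolar carcinoma (8250) is grouped with the adenocarcinomas,
which it is a variant of, rather than under "other specific carcinomas"
where the 2004 ranges place it. Registries with a different dialect can
swap the range file without touching code.

## Cohort selection and person-time

Defaults describe a lung-cancer survivor cohort: ICD-10 prefix `C34`,
diagnosis years 2002–2013, exclusion of morphologies 8263, 8290, 8720,
8815, 8933, 9050 and 9133 (likely miscoded metastases), no
death-certificate-only (DCO) index cases, a 6-month survival landmark, and
follow-up from the landmark to the earliest of first counted second
primary, death, 2014-12-31, or 13 years after diagnosis. Exclusion reasons
are assigned in a fixed precedence order (site, period, morphology, DCO,
landmark, age) so the audit log is deterministic; the age filter has no
default bounds and is applied only when configured. Durations are whole
days divided by 365.25; ages are completed years, with band transitions on
the birthday itself (a Feb 29 birthday rolls to Mar 1 in non-leap years).

Person-time is tabulated by splitting each at-risk interval at every
band-boundary birthday, calendar-period boundary and (optionally)
follow-up-window boundary; fragments accrue to the stratum of their start
date. The algorithm is validated against an independent day-by-day
accumulation oracle to 1e-9 person-years, and conservation (table total =
summed interval lengths) holds under any band refinement. Non-lung second
primaries do not censor the lung-specific at-risk interval; on data where
registered same-site events exist (SEER-style input), a registered
same-group event does end at-risk time under `sir2_sub` even though it is
not counted as observed — the patient then has two registered primaries.
The unspecified index stratum is included in `sir2_sub` totals by default
(`include_unspecified = FALSE` drops it; risk after an unspecified index
is structurally under-estimated under IARC/IACR registration either way).

## Multiple-primary rule engines

The IARC dialect counts a later same-site tumor (site = identical ICD-10
3-character prefix; sub-sites of C34 do not separate primaries) only when
its group differs from every previously counted tumor in that site, with
the unspecified wildcard matching everything. The SEER-style dialect
implements the three clauses that drive the contrast for lung: a new
primary after ≥ 3 disease-free years, a third-digit histology difference,
or differing laterality with both sides known. It is deliberately *not*
the full SEER MP/H rulebook. Same-day ties are broken by ascending
morphology then input order, purely so the adjudication is deterministic
and testable.

## What the synthetic registry emulates — and what it does not

`generate_cohort()` draws, per person: sex (default 32% female), age at
diagnosis from a normal distribution (mean 68, SD 10, truncated to 30–99
years), a uniform diagnosis date in 2002–2013, a region, an index histology
group from the configured distribution, exponential post-diagnosis
survival (median 1.5 years, matching a mostly short-surviving lung-cancer
cohort), and a second-primary waiting time that is piecewise-exponential
over age bands with hazard `sir_real ×` the configured background rate,
starting at the 6-month landmark (no second primary inside the latency
window, keeping generated truth aligned with the analysis window). The
second tumor's histology is drawn independently from the same distribution,
as the bias model assumes. With `apply_iarc_suppression = TRUE`, second
primaries an IARC/IACR registry could not record (same group as the index,
or either tumor unspecified) are deleted from the output — they occurred,
but the registry cannot see them; the suppressed count is reported as
ground truth. The seed fully determines the output, and toggling
suppression alone changes no other record.

Default background rates rise step-wise with age from 2 per 100,000
person-years below 40 to 350 per 100,000 at 80+, a realistic order of
magnitude for lung-cancer incidence; the same step function doubles as the
general-population first-cancer incidence, so
`generate_population_denominators()` (population person-time plus an
incident-case roster, mortality ignored) reproduces the configured rates in
the large-population limit, and `rate_table_from_config()` supplies the
exact infinite-population rate table through the package's external
rate-table path — the analogue of registry-wide rates computed from a
population vastly larger than the cohort, and free of Monte-Carlo noise.

The default histology distribution is
(squamous .42, adenocarcinoma .32, small-cell .12, large-cell .05,
other carcinoma .05, sarcoma .02, other specified .02, unspecified 0),
giving `Σ p_j² = 0.2986` and hence ≈ 30% conventional-SIR shortfall, the
regime of interest for lung cancer. It deliberately puts zero mass on the
wildcard unspecified group: unspecified histology creates residual bias
that no estimator of this family can remove (a wildcard second primary is
unregistrable after *any* index tumor), so ground-truth recovery is only a
clean benchmark without it. Setting a positive unspecified share is the
supported way to study that residual bias rather than a validated default.

DCO status is drawn independently among decedents (4% by default), and a
DCO patient's second primary is unregistered along with them, so DCO
removal thins events and person-time proportionally. An earlier design —
flagging only event-free decedents — makes DCO exclusion informative and
biases every variant upward by a few percent; the chosen model keeps the
flag non-informative, which is also how registries understand DCO (a
registration artifact, not a clinical state).

The generator is structural, not demographic: it matches no country's
marginal incidence, models one second primary per person (after a
suppressed event the person stays "at risk" in the registry's eyes but can
produce no further event — a < 0.5% thinning at the default event rates),
uses the same background hazard for both sexes, and ignores population
mortality in the denominators. Passing tests therefore demonstrate the
estimators' statistical correctness under the stated generating model, not
calibration to any real registry.

## Validation workloads

The test suite exercises, among others: the closed form exactly
(`0.75 × SIR_real` for a uniform four-group distribution, at true ratios
1.0, 2.0, 3.38, 4.85, with linearity to machine precision); agreement of
the closed form with full event-level simulation within three Monte-Carlo
standard errors (20 replicates × 50,000 persons); recovery of a true ratio
of 2.0 on 100 suppressed cohorts of 100,000 persons — the
histology-specific CI covers the truth in ≥ 90 runs while the conventional
estimate falls below it in ≥ 95 and its mean shortfall matches
`1 − Σ p_j²` ≈ 30%; exactness of the Poisson interval against an
independent gamma-quantile oracle and its empirical coverage over 10,000
draws; the multiple-primary truth table plus a 1,000-patient no-same-group
invariant; and the person-time oracle on 50 randomized cases. These sizes
were chosen so each Monte-Carlo margin is several times its standard
error. `scripts/acceptance.R` re-runs a condensed version (20 replicates ×
50,000 persons for recovery) and writes the resulting quantities as JSON.

## Known limitations

* If second primaries are missing from the data for other reasons
  (incomplete registration, trace-back failure), every variant still
  under-estimates risk; the histology-specific correction addresses
  MP-rule suppression only.
* The method is informative only where incidence spreads across histology
  groups; for entities dominated by a single group (`max p_j → 1`) the
  same-group exclusion removes almost everything.
* The unspecified-histology index stratum remains structurally
  under-estimated under IARC/IACR registration; both inclusion and
  exclusion of that stratum are supported and reported explicitly.
* The SEER-style engine covers the narrated timing/third-digit/laterality
  clauses, not the complete SEER MP/H rulebook.
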