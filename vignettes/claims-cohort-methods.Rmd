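---
title: "Methods: claims-based cohort construction and care-pathway derivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based cohort construction and care-pathway derivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortpath)
```

## Scope and data model

`cohortpath` constructs an early-breast-cancer cohort from
reimbursement-claims tables: one patient table (sex, birth date,
insurance plan, vital status, death date, inclusion date) and one event
table in which every row is a dated claim line tagged with a code system
(ICD-10 diagnoses, CCAM procedures, ATC drugs, long-term-illness ICD-10)
and a care context (hospital/outpatient). Drug codes are assumed
normalised to ATC before ingestion — both outpatient presentation codes
and in-hospital dispensing-unit codes map onto ATC, and the pipeline
reasons only in ATC. All date arithmetic is in whole days; claims have
day granularity, so nothing finer is meaningful.

Every rule is driven by a *code dictionary*: named sets of
`SYSTEM:CODE` pairs (diagnosis codes, the five surgery categories,
session codes, molecule codes, diagnostic-procedure codes). The shipped
default uses synthetic placeholder CCAM codes and public ATC molecule
codes, because the operational code lists used on the real national
database are not redistributable; a site substitutes its own lists via
a JSON file without touching any logic. The dictionary enforces two
structural invariants: the five surgery sets are pairwise disjoint, and
the three endocrine-therapy molecule sets are pairwise disjoint.

## Selection: ten ordered filters

Filters are applied in a fixed order and each excluded patient is
attributed to the *first* filter that rejects her, which makes the
attrition report deterministic; the order-of-application convention is
ours (the source selection procedure does not specify attribution for
multi-reason patients). The filters: (1) at least one breast-cancer
diagnosis code; (2) inclusion date in the 2011-2017 incidence window;
(3) female; (4) age ≥ 18 at inclusion; (5) general insurance plan;
(6) breast surgery within 365 days of inclusion; (7) no other-cancer
code in the observation window; (8) no breast-cancer code in the 365
days before inclusion; (9) no metastasis code in the
stage-IV-suspicion window; (10) chronological consistency.

Two filters needed operational definitions that the available material
leaves open, and both are configuration, not logic:

* **Stage-IV suspicion (9).** Any code from the metastasis set within
  `[inclusion − 365 d, index surgery + 180 d]`. The window mirrors the
  nodal-status window around surgery plus the one-year look-back; the
  metastasis set excludes the node-disease code used for nodal status.
* **Data quality (10).** Claims after the recorded death date, or
  surgery before birth. Patients with no computable index anchor at
  filter 9 fall back to the inclusion date as anchor (they are excluded
  at filter 6 anyway, so the choice is inert).

## Treatment detection

The **index surgery** is the earliest breast surgery proper (total or
partial mastectomy, with or without axillary surgery; axillary surgery
alone never qualifies) between January 1 of the inclusion year and 365
days after inclusion. Patient-level surgery type is binned
most-extensive-wins over all surgery events of that window: any total
mastectomy ⇒ mastectomy; any axillary component ⇒ axillary surgery.
Same-day code ties resolve the same way, which is the standard
multi-code-stay convention.

Detection windows are closed on both ends — "between X before and up to
Y after" reads inclusive — and membership is a pure function of
`event date − index date`: radiotherapy `[-150, +365]`, chemotherapy
`[-250, +180]`, targeted therapy `[-250, +180]`, nodal status
`[-250, +180]` days. Sessions strictly before the index date are
neoadjuvant; sessions on or after it, including same-day sessions, are
adjuvant (a same-day session is read as immediate post-operative
administration; the source is silent on ties). Radiotherapy and
chemotherapy may be `neoadjuvant`, `adjuvant` or `both`; endocrine and
targeted therapy are `neoadjuvant_then_adjuvant` whenever any pre-index
delivery exists, else `adjuvant` — their post-surgery continuation is a
single course, not a separate adjuvant one.

**Chemotherapy regimens.** Molecule flags are read from drug codes
delivered on in-window session dates (same-date linkage; the linkage
rule in the source's appendix is unavailable, and same-date matching is
the conservative choice the generator also uses). The seven-way
decision table: anthracycline+paclitaxel, paclitaxel only,
anthracycline+docetaxel, docetaxel only, anthracycline only, any other
coded combination → `other`, no molecule codes at all → `unknown`. The
`unknown` class is structural, not an error: regimens delivered without
per-molecule coding (anthracycline- and/or docetaxel-based courses
administered purely as hospital sessions) are not identifiable, while
paclitaxel-containing regimens are.

**Cycles.** Within each setting, sessions merge into one cycle when
closer than 7 days; the gap is configurable and 7 days is the shortest
standard inter-cycle interval (weekly paclitaxel), so that a two-day
infusion spill-over never splits a cycle.

**Endocrine therapy** is detected from outpatient dispensings of
tamoxifen, aromatase inhibitors or GnRH agonists from 250 days before
the index surgery onward, with one exclusion: a GnRH-agonist delivery
within 30 days before chemotherapy start in a patient who never
receives tamoxifen or an aromatase inhibitor is read as fertility
preservation, not endocrine therapy, and discarded. The course ends one
dispensing interval (30 days, one pack) after the last delivery. The
seven regimen categories follow molecule presence plus single-switch
"followed by" semantics: every delivery of the first molecule must
precede every delivery of the second; GnRH alone, three-molecule
histories and multi-switch sequences fall into `others`.

**Targeted therapy** is trastuzumab/pertuzumab sessions in the
chemotherapy window; any pertuzumab code makes the regimen
`pertuzumab +/- trastuzumab`. The six-way combination classification is
operationalised at regimen level: the chemotherapy regimen label plus a
≥ 1-day overlap of the two course date ranges decides classes 1-4
(anthracyclines/docetaxel-TT, anthracyclines/paclitaxel-TT,
docetaxel-TT, paclitaxel-TT in the Tolaney sense), targeted therapy
with endocrine therapy and no chemotherapy is class 5, and everything
else — including unknown chemotherapy regimens — is `other`. Phase-level
concurrency (anthracycline phase first, then taxane plus targeted
therapy) is not reconstructed because courses carry one date range per
modality; the regimen label already encodes the phase structure.

## Dating the diagnosis

First treatment is the earliest of the index surgery and the start of
any neoadjuvant component. The diagnosis is then dated by precedence:
earliest core biopsy within 365 days before first treatment; else
earliest cytology in the same window; else a backward walk through
imaging procedures starting at the one closest to (and not after) first
treatment, continuing while consecutive gaps are ≤ 30 days, returning
the earliest procedure reached; else the first-treatment date itself.
"A month" is fixed at 30 days and "12 months" at 365 days (both
configurable); the biopsy/cytology window is closed at the treatment
date. Age at diagnosis is the half-up-rounded difference in
365.25-day years — half-up rather than banker's rounding because a
"rounded difference in years" reads as the everyday convention, and the
365.25-day year absorbs leap years.

## Phenotyping and pathways

Subtype is a treatment proxy on an 8-cell truth table: targeted therapy
⇒ HER2+, split by endocrine therapy into HR+/HR−; endocrine without
targeted ⇒ luminal; chemotherapy alone ⇒ TNBC; none of the three ⇒
undefined. The canonical sequence has nine slots (NAC, NTT, NRT, NET,
surgery, adjuvant CT, TT, RT, ET); `both`-setting radiotherapy or
chemotherapy fills both its slots, while a continued
neoadjuvant-then-adjuvant endocrine or targeted course fills only its
neoadjuvant slot. The main pathway applies NAC > NRT > NET precedence;
patients with no neoadjuvant component split by adjuvant chemotherapy
into surgery-then-CT vs surgery-without-CT. NRT-only is kept as an
explicit fifth, rare class rather than folded into "other", so pathway
counts always partition the cohort. Endocrine re-initiation after a
neoadjuvant course is treated like continuation (not adjuvant): the
course is one object and the caption rule for continuation is applied
uniformly.

## Reporting

Summary blocks carry their denominator explicitly: whole cohort for
treatment yes/no, subtype (undefined included), nodal status and
surgery bins; the treated subset for settings and regimens; the
defined-subtype subset for subtype shares. Chemotherapy regimens are
reported per *setting*, so a both-setting patient counts twice —
`n_neo + n_adj + 2 × n_both` — which reproduces the published
denominator arithmetic (15,627 + 72,939 + 2 × 1,686 = 91,938).
Percentages are rounded half-up to one decimal, matching table display
conventions, so block percentages sum to 100 ± 0.1. Trend displays
suppress strata with fewer than 50 patients.

**Multimodality.** The critical-bandwidth test is implemented directly:
the critical bandwidth `h*` is the smallest Gaussian-KDE bandwidth with
at most `k` modes, found by bisection on a scale-equivariant bracket
(relative tolerance 1e-4, mode counting on a 512-point FFT grid); the
p-value is the fraction of smoothed bootstrap resamples
(variance-rescaled, drawn from the KDE at `h*`) whose KDE at `h*`
exceeds `k` modes. Defaults: 500 seeded replicates; fewer than 100
warns. A constant sample is unimodal with p = 1 by convention. Because
the bracket, the grid and the resampling are all scale-equivariant, the
p-value is invariant under affine rescaling of the input. The number of
modes under the alternative is a *parameter* (`alt_modes`, default
`null_modes + 1`): the original procedure assessed the mode count
graphically, and we expose the choice rather than automate it. Mode
locations are the KDE maxima at the critical bandwidth for that count.
Equivalence with packaged implementations of the test is asserted at the
level of reject/retain decisions on clear cases, not p-value equality,
since "critical bandwidth" admits implementation variants.

**Survival.** Overall survival runs from the index surgery to death or
the 2019-03-01 cutoff, in months of 30.4375 days (follow-up is reported
in months with no stated conversion rule, so the average Gregorian
month is used). Product-limit curves and log-rank tests are delegated to
the `survival` package; the test suite cross-checks the estimator
against an independent brute-force product-limit computation to 1e-12.
Median follow-up and its IQR come from reverse Kaplan-Meier (censoring
as the event). With zero events the log-rank is reported as not
applicable rather than an error.

## The synthetic-claims generator

The generator is the inverse of the inference maps above, so that label
recovery is well defined: treatments are generated *from* the subtype
(luminal ⇒ endocrine therapy, TNBC ⇒ chemotherapy without endocrine or
targeted therapy, HER2+ ⇒ targeted therapy ± endocrine therapy,
undefined ⇒ surgery ± radiotherapy only), pathways conditional on
subtype place the chemotherapy/endocrine/radiotherapy blocks on the
correct side of the index surgery, and contaminants carry exactly one
filter-tripping pattern each (male sex, under-age, non-general plan,
missing surgery, other-cancer code, prior breast-cancer code,
metastasis code, claims after death). With the default zero treatment
noise the full pipeline must recover subtype, pathway and setting
labels with a confusion matrix equal to the identity — and the
acceptance suite asserts exactly that.

Default study conditions: age at diagnosis from a two-component
Gaussian mixture with means 50.3 and 65.0 years (the two incidence
peaks the cohort is known for; weights 0.5/0.5 and standard deviations
5 years are our emulation choice, not fitted values); the `realistic`
preset uses subtype shares 0.802/0.095/0.103 (luminal/TNBC/HER2+,
HER2+ split 0.637/0.363 into HR+/HR−) among defined subtypes with an
undefined share of 0.189, and a 4.5% metastatic-contamination rate
consistent with published stage-IV exclusion rates. No joint
distribution of age × subtype × pathway is published, so the generator
uses independence given subtype, and says so. Death times come from
per-subtype exponential hazards censored at 2019-03-01 — a minimal
model sufficient to exercise the survival code, not a calibrated one;
a drawn death date is pushed past the patient's last claim so that
included records stay chronologically consistent (only the explicit
`corrupt` contaminants violate chronology). Endocrine dispensings are
emitted every 30 days (monthly pack reimbursement) for 60 months;
when the administrative cutoff truncates a plan before its molecule
switch, the ground-truth regimen label is relabelled to the molecules
actually delivered, so truth always describes the emitted stream.

What the generator does **not** emulate: comorbidity coding, coding
errors and inter-centre coding discrepancies, treatment refusal and
non-compliance, real attrition proportions, calendar-time practice
trends, or any correlation structure beyond subtype-conditional
independence. Passing the recovery tests therefore shows the pipeline
is a correct implementation of its rules, not that the rules have any
particular sensitivity or specificity on real claims — the latter is
unknowable without the restricted database.

## Problem sizes and numerical choices

The test suite runs the recovery property at n = 2,000 (acceptance
script: 5,000), filter attrition at n = 5,000, the Kaplan-Meier
cross-check on 100 random datasets of n ≤ 30, and the multimodality
test at n = 5,000 with 500 bootstrap replicates — sizes chosen so the
whole suite runs in well under a minute per property on one CPU while
keeping binomial noise far from every asserted threshold. All
randomness is seeded; the generator restores the caller's RNG state.

## Known limitations

Subtype is unclassifiable for patients who refuse endocrine therapy or
whose HER2+ tumours go untreated; claims cannot distinguish
targeted-therapy-alone sessions from combined chemotherapy sessions;
the exact operational definitions of filters 7-10, cycle counting,
regimen inference and the fertility-preservation exclusion in the
original procedure live in material that is not redistributable — the
package's explicit, configurable stand-ins are documented above and
should be revisited against the authoritative definitions where
available.
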