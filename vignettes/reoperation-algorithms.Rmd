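---
title: "Identifying reoperations and their causes in coded registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying reoperations and their causes in coded registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopalg)
library(dplyr)
```

## The problem

Administrative discharge registers record every hospital contact with
ICD-10 diagnoses (Danish dialect: leading `D`, no dot, e.g. `DT846`) and
NOMESCO surgical procedures (leading `K`; `KNGJ21` decomposes as chapter
`KN` = musculoskeletal, region `G` = knee/lower leg, then the procedure
stem). After a fracture osteosynthesis, the *occurrence* of a later
operation is captured well in such data, but the *reason* for it is not:
surgeons often code a revision with nonspecific procedure stems, and the
specific complication codes are used in only a fraction of true cases.
This package implements a register-side phenotyping pipeline — identify
candidate reoperations, classify their cause with code-set algorithms,
quantify the accuracy of those algorithms against a gold standard — plus
the stepwise procedure by which such algorithms are constructed, and a
synthetic registry so all of it is testable without restricted data.

## Identifying candidate reoperations

A contact qualifies as a candidate reoperation for an index fracture when
all four conditions hold:

1. **Surgical chapter** — at least one procedure code in chapter `KA`
   (nervous system), `KN` (musculoskeletal) or `KQ` (skin).
2. **Window** — between day 1 and day 365 after the index surgery. Day 0
   is never a reoperation: same-day codes belong to the index contact, and
   the index procedure must not match itself. The window is the half-open
   day interval (0, 365].
3. **Same anatomical area** — the contact's region letter equals the index
   region. `KN` codes carry the region at position 3; for `KQ`/`KA`
   chapters there is no universal convention, so the mapping is
   configurable and defaults to "position-3 letter if in `B`–`H`,
   otherwise region-neutral". Region-neutral codes pass for any index
   region; this is the permissive reading of "same anatomical area", and a
   stricter site can supply its own chapter table.
4. **Laterality** — the contact side equals the index side, or either is
   unspecified. Missing side coding is common in discharge data, so
   missingness never blocks a match, and an index with unspecified side
   accepts all contacts. A contact's side is the unique specified side
   among its coded events; conflicting sides within one contact are
   treated as unspecified.

Codes sharing a contact identifier form one candidate; two contacts on the
same day remain separate candidates, because reoperations are counted as
procedures, not as codes.

Planned removal of K-wires or external fixators and care for chronic foot
ulcers, decubitus and venous disease are not reoperations. These
exclusions are purely code-set-based (codes cannot distinguish a planned
from an unplanned removal) and live in the same editable configuration as
the cause algorithms. The shipped stems (`KNxU19`, `KNxU49`, `DL97`,
`DL89`, `DI83`) are deployment placeholders: national registries do not
share a single convention here, and any site should review them. A
`procedure_only` exclusion fires only when *every* qualifying surgical
code on the contact matches, so a contact that also performed genuine
revision surgery is retained; diagnosis-driven exclusions
(`diagnosis_any`) fire on any matching diagnosis.

## Classifying the cause

Causes are evaluated per candidate in descending severity and the first
match wins: **infection** (procedure `KNxW69`/`KNxW59` or diagnosis
`DT846`), **nonunion** (`KNxT5`, `DT813O`, `DM841`), **early
re-osteosynthesis** (revision fixation `KNxJ` or prosthetic conversion
`KNxC` within 42 days; mechanical-complication diagnoses
`DT840`–`DT844`), **secondary arthroplasty** (`KNxC` after day 42),
**hardware removal** (`KNxU` from day 42), **wound treatment** (any `KQ`
procedure), and **other** as the total fallback — every retained candidate
gets exactly one label. Two consequences of the ordering are intentional:

* A `KQ` wound procedure accompanied by infection evidence classifies as
  infection, so "wound treatment" is by construction wound care
  *unrelated* to infection.
* "Secondary arthroplasty not caused by nonunion or infection" is
  enforced at the fracture level by the severity roll-up rather than by
  candidate-level exceptions: when one fracture has several reoperations,
  the fracture keeps the most severe cause (infection > nonunion >
  re-osteosynthesis > secondary arthroplasty > hardware removal > wound
  treatment > other).

**The 6-week threshold is fixed at 42 days** with boundary assignment
day ≤ 42 → early re-osteosynthesis and day > 42 → secondary arthroplasty,
so the two can never both fire for one candidate; hardware removal counts
*from* day 42 ("at least 6 weeks"). The source descriptions alternate
between "within", "after" and "at least" 6 weeks; this single cut with
these inequalities is the unique choice that keeps the partition exclusive
while honouring all three phrasings.

All code matching is prefix-based (`KNxU` catches full removal codes such
as `KNGU29`), with the wildcard `x`/`X` standing for any of the seven
region letters, and contiguous diagnosis ranges (`DT840`–`DT844`) matched
lexicographically on the prefix of the range's length. Codes are
uppercased on ingest.

## Constructing algorithms stepwise

Where a gold standard is available (chart review, or the synthetic
generator's labels), algorithms are *built*, not assumed:

1. Each candidate code family is scored by the likelihood-ratio statistic
   of the univariate logistic regression of the gold label on "family
   fires", signed by direction of association. The closed-form 2×2
   statistic is used, which is identical to the iterative fit but exact
   under complete separation, making ranking fully deterministic. We read
   the construction as *univariate* scoring followed by cumulative
   composition — not multivariable selection — because steps are code
   additions under "or", not coefficient thresholds. Ties break by higher
   PPV, then by name; never-firing families score zero and sort last.
2. Step *k* classifies a fracture positive when any of the top-*k*
   families fires. Adding a family can only add positives, so sensitivity
   and the test-positive count are non-decreasing in *k*, while PPV
   typically falls.
3. Every step is scored with the full accuracy report, and the deployed
   step maximizes Cohen's kappa; on ties the smallest step wins
   (parsimony — the choice is otherwise open).

Major/minor composite algorithms take the union of their constituents'
selected steps and are scored against the composite gold label.

The shipped per-cause defaults contain the code families with established
identities listed above; full deployed step lists are site-specific, so
the configuration round-trips through YAML/JSON and is replaceable without
code changes (`read_code_config()`, `write_code_config()`).

## Accuracy statistics

* Sensitivity `100·tp/(tp+fn)`, PPV `100·tp/(tp+fp)`, specificity
  `100·tn/(tn+fp)`, NPV `100·tn/(tn+fn)`; all reported in percent.
  Zero-denominator metrics propagate as `NA`, never as 0 or an error.
* **Clopper–Pearson** exact intervals via the beta-quantile
  characterization: lower bound `qbeta(α/2, x, n−x+1)` (0 at x = 0),
  upper `qbeta(1−α/2, x+1, n−x)` (1 at x = n); default level 95%. This
  equals inverting the exact binomial test at α/2 per tail, which the test
  suite verifies against a brute-force root-finding oracle.
* **Cohen's kappa** `(p_o − p_e)/(1 − p_e)` from the 2×2 marginals,
  returning 1 for the degenerate perfect one-class table.
* **AUC of a deployed binary rule** is balanced accuracy,
  `(se + sp)/2` on the fraction scale: a single rule contributes one ROC
  point, and the area under the two-segment curve through it is exactly
  this. Full ROC traces across steps come from the step-trace table, not
  from a single 2×2.
* Display rounding follows validation-report convention (integer percent,
  two decimals for kappa/AUC); machine output keeps full precision.

`validation_counts()` ships the printed confusion counts from the national
validation study of these algorithms (11,551 fractures, 2,347 reviewed
reoperations) in the marginal/diagonal layout such reports use, and
reconstructs the four cells as `tp = TrP`, `fp = TP − TrP`,
`fn = TN − TrN`, `tn = TrN`. This reading reproduces the published
sensitivity, PPV, kappa and AUC for the infection, nonunion,
re-osteosynthesis, wound and minor rows, which is why it is adopted. Three
printed values are not reproducible from their printed cells under any
reconstruction we tried (the major-reoperation and hardware-removal
kappas, and the minor-reoperation AUC), and the printed
secondary-arthroplasty diagonal exceeds its margin, which is impossible;
that row's cells are rebuilt from its gold-standard total, and the
non-reproducible values are simply not asserted anywhere. The published
wound PPV (83) also disagrees by one display unit with its printed cells
(621/753 = 82.5 → 82), so only the wound sensitivity is checked.

## The synthetic registry

`simulate_registry()` draws, per fracture: a region (mix proportional to
the relative primary-surgery volumes across the seven regions), a side, an
index date and osteosynthesis code; a true cause at the configured
prevalences (defaults are one-year cumulative incidences per population at
risk: hardware removal 7.5%, wound treatment 5.4%, re-osteosynthesis 1.7%,
other 1.2%, infection 1.0%, secondary arthroplasty 0.8%, nonunion 0.8%); a
reoperation day *uniform* within the cause's admissible window (≤ 42 days
for re-osteosynthesis, > 42 for secondary arthroplasty, ≥ 42 for hardware
removal, anywhere in (0, 365] otherwise — no published timing
distributions exist, so uniform is the simplest window-consistent choice);
and contact codes through the coding-error model. `validation_cohort_config()`
instead scales prevalences to the reviewed-reoperation mix, which is the
right substrate for exercising algorithm construction.

The coding model is per cause: probabilities of the correct procedure
code, the correct diagnosis code, and both, with `p_both` binding
(defaults: infection 0.26/0.33/0.10, nonunion 0.18/0.11/0.08,
re-osteosynthesis 0.99/0.07, secondary arthroplasty 0.03, hardware removal
0.99, wound treatment 0.99 — the reported code-usage rates). The reported
"either one or the other" rates over-determine the model jointly with
`p_both`; we treat `p_both` as binding, and the implied either-or rates
(`p_proc + p_diag − p_both`: 0.49 infection, 0.21 nonunion) land close to
the reported 50%/22%, which the calibration tests check. When a correct
code is suppressed, the contact still carries a nonspecific surgical code
from a decoy pool (`KNxB9…` stems), so identification-stage sensitivity is
1 by construction and only *cause* coding degrades — deliberately
mirroring how real registers fail. The decoy pool's overlap with cause
patterns is a knob (`decoy_overlap`: the probability that a decoy is drawn
from a revision-fixation stem colliding with the early re-osteosynthesis
patterns rather than from the neutral pool), because the false-positive
structure of real registries is unknown; at the default of 0, cause-level
false positives are zero by construction and the only identification
false positives come from noise contacts.

Noise contacts (per-fracture rates calibrated to the validation study's
false-positive composition: ER visits 0.9%, new fractures 0.16%, chronic
wounds 0.11%, K-wire removals 0.64%, fixator removals 0.1%, contralateral
surgery 1.2%) carry no cause-specific codes on the index side. Options:
`p_second_reop` adds a later hardware-removal contact to fractures with a
major cause (exercising the severity roll-up without changing gold
labels), and `censoring_rate` truncates follow-up at a uniform day,
relabelling fractures censored before their reoperation as true
negatives — death before a planned reoperation, off by default.

What the generator does **not** emulate: real Danish contact
microstructure (transfers, outpatient series, multi-department
admissions), patients contributing several fractures, correlated coding
behaviour within hospitals, seasonal or regional variation, and any
calibration to patient-level data. Passing tests therefore demonstrate
that the *pipeline logic* is correct under the stated error model — they
do not validate the shipped code sets against any real register, which
always requires site-specific chart review.

## Numerical and degenerate-input choices

* Seeds: generation restores the caller's RNG state; a fixed seed gives
  bit-identical cohorts.
* Dates are ISO-8601 at day resolution throughout; ingest rejects (and
  reports, line-numbered) rather than silently drops malformed rows.
* `worst_cause()` of an empty set, negative confusion cells, prevalences
  summing above 1, `p_both > min(p_proc, p_diag)` and a `selected_step`
  beyond the step list are errors; undefined metrics are `NA`.
* Problem sizes in the test suite are chosen for tight binomial
  tolerances where rates are asserted (20,000 fractures for calibration
  checks, with the infection share raised to 0.5 so the Monte-Carlo error
  of a rate is well under 0.02) and for speed elsewhere (a few hundred
  fractures); the stepwise-gain check runs 20 replicates at the
  validation-cohort size of 2,347.

## Known limitations

* The shipped cause code sets are the main-text families only; deployed
  algorithms in production used longer site-tuned lists, so absolute
  synthetic accuracies with shipped defaults understate what tuned
  configurations achieve (most visibly for secondary arthroplasty, where
  the correct procedure code is used in 3% of true cases).
* Infected nonunions cannot be separated from aseptic ones in codes
  alone; the severity order resolves them as infection when infection
  codes are present.
* Reoperations absent from the input (performed abroad, missing records)
  are invisible at identification time; the generator's censoring knob
  models loss to follow-up, not record unavailability.
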