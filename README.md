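# reopalg

Phenotyping algorithms for **reoperations after fracture surgery** in coded
health-administrative data.

National discharge registers (the Danish National Patient Register and its
Nordic siblings) record every hospital contact with ICD-10 diagnosis codes
and NOMESCO procedure codes. They are complete and cheap, which makes them
attractive for studying surgical complications — but the codes for *why* a
reoperation happened are unreliable: in validation work against chart
review, the correct infection procedure codes (`KNxW69`/`KNxW59`) appear in
only 26% of true infections, and the correct diagnosis (`DT846`) in 33%.
`reopalg` implements the register-side machinery for working with such data
anyway:

- **Identification** — a reoperation is any contact carrying a surgical
  procedure code in the nervous-system (KA), musculoskeletal (KN) or skin
  (KQ) chapter, in the *same anatomical area* as the index surgery (the
  region letter at position 3 of a NOMESCO code, `KNG` = knee/lower leg),
  on a *compatible side* (same side, or missing laterality), within
  **365 days** of the index procedure. Planned K-wire/external-fixator
  removal and chronic-wound care are excluded by configurable code sets.
- **Cause classification** — stepwise code-set algorithms label each
  reoperation as infection, nonunion, early re-osteosynthesis (≤ 42 days),
  secondary arthroplasty (> 42 days), hardware removal (≥ 42 days), wound
  treatment, or other; competing causes resolve by a fixed severity
  hierarchy, and fractures roll up to major/minor composites.
- **Algorithm construction** — candidate code families are ranked by
  univariate logistic association with a chart-review gold standard and
  composed cumulatively with "or". Step *k* fires when any of the top-*k*
  families fires, so sensitivity is non-decreasing while PPV falls; the
  deployed step maximizes Cohen's kappa.
- **Diagnostic accuracy** — sensitivity, PPV, specificity and NPV as
  percentages with exact Clopper–Pearson intervals
  (`sens = 100·tp/(tp+fn)`, `ppv = 100·tp/(tp+fp)`), Cohen's kappa, and
  the AUC of a deployed binary rule (balanced accuracy,
  `(se + sp)/2`).
- **Synthetic registry** — a generator with known ground truth: index
  surgeries across the seven anatomical regions, true causes at realistic
  one-year cumulative incidences, a per-cause coding-error model, noise
  contacts (ER visits, new fractures, chronic wounds, wire removals,
  contralateral surgery), and optional censoring. Everything downstream is
  testable without access to any real register.

All user-facing functions take and return tibbles and chain with the pipe.

## Worked example

Simulate a validation-style cohort (2,347 fractures with the reviewed
reoperation mix), run the pipeline, and score it against the generator's
gold labels:

```r
library(reopalg)
library(dplyr)

cohort <- simulate_registry(validation_cohort_config(seed = 2024))
cohort
#> Synthetic registry cohort: 2347 index fractures, 4400 coded events (seed 2024)
#>   true_cause                 n
#> 1 hardware_removal         846
#> 2 wound_treatment          626
#> 3 not_reoperation          224
#> ...

fractures <- classify_cohort(cohort$events, cohort$index)
evaluate_causes(fractures, cohort$gold) |>
  select(target, sensitivity, ppv, kappa, auc, tp, fp, fn, tn)
#>   target          sensitivity   ppv kappa   auc    tp    fp    fn    tn
#> 1 any_reoperation       100   100.0 0.998 0.998  2123     1     0   223
#> 2 major                  54.4 100   0.652 0.772   277     0   232  1838
#> 3 minor                  99.0 100   0.986 0.995  1457     0    15   875
#> ...
```

Identification is essentially perfect (every true reoperation produces a
qualifying contact), while *cause-level* sensitivity is limited by the
coding-error model — exactly the failure mode these algorithms exist to
mitigate. Build the infection algorithm stepwise and watch the "or"
composition buy sensitivity:

```r
cand <- find_reoperations(cohort$events, cohort$index) |> apply_exclusions()
groups <- list(
  infection_procedure = code_pattern(c("KNxW69", "KNxW59")),
  infection_diagnosis = code_pattern("DT846")
)
fires <- pattern_fires(cand, cohort$index, groups)
gold <- cohort$gold$true_cause[match(fires$fracture_id,
                                     cohort$gold$fracture_id)] == "infection"
build_stepwise(fires, gold)
#> Stepwise code-set algorithm (2 steps, selected step 2)
#>     step 1 + infection_diagnosis   sens  33.3  ppv 100.0  kappa 0.487
#>   * step 2 + infection_procedure   sens  47.2  ppv 100.0  kappa 0.628
```

Each single code family finds a third of infections or less; their union
finds almost half. `autoplot()` on the trace draws the
sensitivity/PPV/kappa trade-off across steps.

Accuracy statistics work directly on published 2×2 counts too. Validation
reports often print test-positive/-negative marginals next to the correct
diagonal; `confusion_from_marginals()` reconstructs the cells:

```r
accuracy_report(confusion_from_marginals(103, 88, 2244, 2218))
#> Diagnostic accuracy (n = 2347)
#>   sensitivity   77.2% (95% CI 68.4-84.5)
#>   ppv           85.4% (95% CI 77.1-91.6)
#>   specificity   99.3% (95% CI 98.9-99.6)
#>   npv           98.8% (95% CI 98.3-99.2)
#>   kappa 0.80, AUC 0.88
#>   cells: tp 88, fp 15, fn 26, tn 2218
```

## Command line

A thin wrapper exposes the stages as subcommands
(`simulate`, `identify`, `classify`, `evaluate`, `build`) over CSV/JSON
files, with a JSON-lines provenance log per run:

```sh
script=$(Rscript -e 'cat(system.file("cli", "reopalg.R", package = "reopalg"))')
Rscript "$script" simulate --n 1000 --seed 7 --out run1
Rscript "$script" classify --events run1/events.csv --index run1/index_surgeries.csv --out run1
Rscript "$script" evaluate --predicted run1/fracture_causes.csv --gold run1/gold_labels.csv --out run1
```

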