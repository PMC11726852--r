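# The published validation table for these algorithms prints marginal
# test-positive / test-negative counts (TP, TN) next to the correctly
# classified diagonal (TrP, TrN); cells reconstruct as tp = TrP,
# fp = TP - TrP, fn = TN - TrN, tn = TrN.
infection_cells <- confusion_from_marginals(103, 88, 2244, 2218)
nonunion_cells <- confusion_from_marginals(138, 77, 2209, 2192)
reost_cells <- confusion_from_marginals(233, 175, 2114, 2094)

unclass_counts <- function(x) c(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)

test_that("confusion tables cross-tabulate aligned label vectors", {
  pred <- c(rep(TRUE, 4), rep(FALSE, 6))
  expect_equal(unclass_counts(confusion_counts(pred, pred)),
               c(tp = 4, fp = 0, fn = 0, tn = 6))
  gold <- c(rep(TRUE, 3), rep(FALSE, 7))
  all_neg <- rep(FALSE, 10)
  expect_equal(unclass_counts(confusion_counts(all_neg, gold)),
               c(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_error(confusion_counts(TRUE, c(TRUE, FALSE)))
})

test_that("marginal reconstruction recovers the four cells", {
  expect_equal(unclass_counts(infection_cells),
               c(tp = 88, fp = 15, fn = 26, tn = 2218))
  # a diagonal exceeding its marginal is impossible
  expect_error(confusion_from_marginals(104, 90, 2234, 2238), "marginal")
})

test_that("proportion metrics round to the published integers", {
  expect_equal(round(sensitivity(infection_cells)), 77)
  expect_equal(round(ppv(infection_cells)), 85)
  expect_equal(round(sensitivity(nonunion_cells)), 82)
  expect_equal(round(ppv(nonunion_cells)), 56)
  expect_equal(round(sensitivity(reost_cells)), 90)
  expect_equal(round(ppv(reost_cells)), 75)
  expect_equal(round(ppv(new_confusion(tp = 2212, fp = 135, fn = 0, tn = 9204))), 94)
  expect_equal(round(sensitivity(new_confusion(5, 0, 0, 1))), 100)
  expect_equal(round(specificity(infection_cells), 1), 99.3)
  expect_equal(specificity(new_confusion(0, 0, 0, 10)), 100)
  expect_equal(npv(new_confusion(0, 0, 0, 10)), 100)
})

test_that("undefined metrics propagate as NA, not zero or error", {
  no_pos <- new_confusion(tp = 0, fp = 0, fn = 0, tn = 10)
  expect_true(is.na(sensitivity(no_pos)))
  expect_true(is.na(ppv(no_pos)))
  expect_equal(ppv(new_confusion(0, 7, 0, 3)), 0)
  rep <- accuracy_report(no_pos)
  expect_true(is.na(glance(rep)$sensitivity))
  expect_true(is.na(glance(rep)$auc))
})

test_that("Clopper-Pearson intervals are exact", {
  ci <- clopper_pearson(88, 114)
  expect_equal(round(ci$estimate), 77)
  expect_equal(round(ci$lower), 68)
  expect_equal(round(ci$upper), 85)

  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 100)

  # oracle 1: stats::binom.test's exact interval
  for (kn in list(c(88, 114), c(3, 10), c(0, 7), c(12, 12), c(45, 60))) {
    ci <- clopper_pearson(kn[1], kn[2])
    ref <- 100 * binom.test(kn[1], kn[2])$conf.int
    expect_equal(c(ci$lower, ci$upper), as.numeric(ref), tolerance = 1e-8)
  }

  # oracle 2: brute-force inversion of the binomial tails at alpha/2
  invert_tails <- function(k, n, alpha = 0.05) {
    lower <- if (k == 0) 0 else {
      uniroot(function(p) pbinom(k - 1, n, p, lower.tail = FALSE) - alpha / 2,
              c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    }
    upper <- if (k == n) 1 else {
      uniroot(function(p) pbinom(k, n, p) - alpha / 2,
              c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    }
    c(lower, upper) * 100
  }
  for (n in c(5, 11, 23)) {
    for (k in 0:n) {
      ci <- clopper_pearson(k, n)
      expect_equal(c(ci$lower, ci$upper), invert_tails(k, n), tolerance = 1e-6)
    }
  }
})

test_that("Clopper-Pearson intervals contain the estimate and tighten with n", {
  for (p in c(0.1, 0.5, 0.9)) {
    widths <- vapply(c(20, 80, 320, 1280), function(n) {
      ci <- clopper_pearson(round(p * n), n)
      expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
      ci$upper - ci$lower
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
  }
})

test_that("Cohen's kappa matches the published values and an independent implementation", {
  expect_equal(round(cohen_kappa(infection_cells), 2), 0.80)
  expect_equal(round(cohen_kappa(nonunion_cells), 2), 0.65)
  expect_equal(round(cohen_kappa(reost_cells), 2), 0.80)
  expect_equal(cohen_kappa(new_confusion(10, 0, 0, 10)), 1)

  # cross-check against e1071's kappa on random tables
  set.seed(4)
  for (i in 1:20) {
    cells <- rmultinom(1, 200, runif(4, 0.05, 1))[, 1]
    counts <- new_confusion(cells[1], cells[2], cells[3], cells[4])
    ref <- e1071::classAgreement(matrix(cells, 2, 2))$kappa
    expect_equal(cohen_kappa(counts), ref, tolerance = 1e-10)
    expect_lte(cohen_kappa(counts),
               (counts$tp + counts$tn) / sum(cells))  # kappa <= po
  }
})

test_that("kappa is near zero when predictions are independent of truth", {
  set.seed(8)
  kappas <- replicate(200, {
    gold <- runif(300) < 0.3
    pred <- runif(300) < 0.5
    cohen_kappa(confusion_counts(pred, gold))
  })
  expect_lt(abs(mean(kappas)), 0.02)  # Monte-Carlo error of the mean ~ 0.004
})

test_that("binary-rule AUC is balanced accuracy", {
  expect_equal(round(binary_auc(infection_cells), 2), 0.88)
  expect_equal(round(binary_auc(reost_cells), 2), 0.94)
  # a chance-level rule: sensitivity = 1 - specificity
  expect_equal(binary_auc(new_confusion(30, 30, 70, 70)), 0.5)
  # invariant to scaling all four cells
  expect_equal(binary_auc(new_confusion(12, 5, 8, 75)),
               binary_auc(new_confusion(36, 15, 24, 225)))
})

test_that("cumulative incidence is cases over population at risk", {
  expect_equal(round(cumulative_incidence(114, 11551), 1), 1.0)
  expect_equal(round(cumulative_incidence(870, 11551), 1), 7.5)
  expect_equal(cumulative_incidence(0, 100), 0)
})

test_that("evaluate_causes produces a row per target with recomputable cells", {
  cohort <- simulate_registry(registry_config(n_fractures = 300, seed = 31))
  fr <- classify_cohort(cohort$events, cohort$index)
  ev <- evaluate_causes(fr, cohort$gold)
  expect_true(all(c("any_reoperation", "major", "minor", "infection",
                    "hardware_removal") %in% ev$target))
  expect_true(all(ev$tp + ev$fp + ev$fn + ev$tn == 300))
  # metrics recompute from the cells
  for (i in seq_len(nrow(ev))) {
    counts <- new_confusion(ev$tp[i], ev$fp[i], ev$fn[i], ev$tn[i])
    expect_equal(ev$sensitivity[i], sensitivity(counts))
    expect_equal(ev$kappa[i], cohen_kappa(counts))
  }
  # id mismatch is a contract violation
  expect_error(evaluate_causes(fr[-1, ], cohort$gold), "same fracture ids")
})
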