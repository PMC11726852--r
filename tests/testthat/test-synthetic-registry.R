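test_that("generation is deterministic for a fixed seed", {
  a <- simulate_registry(registry_config(n_fractures = 200, seed = 77))
  b <- simulate_registry(registry_config(n_fractures = 200, seed = 77))
  expect_identical(a$events, b$events)
  expect_identical(a$index, b$index)
  expect_identical(a$gold, b$gold)
  c <- simulate_registry(registry_config(n_fractures = 200, seed = 78))
  expect_false(identical(a$events, c$events))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(runif(0))
  invisible(simulate_registry(registry_config(n_fractures = 50, seed = 99)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("configuration is validated", {
  expect_error(registry_config(n_fractures = 0), "at least 1")
  prev <- default_cause_prevalences()
  prev["hardware_removal"] <- 0.9
  expect_error(registry_config(cause_prevalences = prev), "sum to at most 1")
  cm <- default_coding_model()
  cm$infection$p_both <- 0.5   # > min(p_proc, p_diag)
  expect_error(registry_config(coding_model = cm), "p_both")
  expect_error(registry_config(laterality_missing_rate = 1.5), "\\[0, 1\\]")
})

test_that("zero prevalences yield a cohort with only noise contacts", {
  prev <- default_cause_prevalences() * 0
  cohort <- simulate_registry(registry_config(
    n_fractures = 300, cause_prevalences = prev, seed = 5
  ))
  expect_true(all(cohort$gold$true_cause == "not_reoperation"))
  expect_true(all(startsWith(cohort$contacts_log$source, "noise_")))
})

test_that("observed prevalences and coding rates match the configured model", {
  # prevalence: exact binomial 99% acceptance band around 0.010
  cohort <- simulate_registry(registry_config(n_fractures = 20000, seed = 55))
  n_inf <- sum(cohort$gold$true_cause == "infection")
  expect_gte(n_inf, qbinom(0.005, 20000, 0.010))
  expect_lte(n_inf, qbinom(0.995, 20000, 0.010))

  # coding rates: boost the infection share so the binomial tolerance is
  # tight (~10,000 true infections give Monte-Carlo error well under 0.02)
  focused <- registry_config(
    n_fractures = 20000, seed = 56,
    cause_prevalences = c(infection = 0.5)
  )
  s <- summarize_cohort(simulate_registry(focused))
  rates <- s$coding[s$coding$true_cause == "infection", ]
  expect_equal(rates$p_correct_procedure, 0.26, tolerance = 0.02 / 0.26)
  expect_equal(rates$p_correct_diagnosis, 0.33, tolerance = 0.02 / 0.33)
  expect_equal(rates$p_both, 0.10, tolerance = 0.02 / 0.10)
  # the implied either-or rate: p_proc + p_diag - p_both ~ 0.49
  expect_equal(rates$p_either, 0.49, tolerance = 0.02 / 0.49)
})

test_that("noise-free cohorts have perfect coding", {
  s <- summarize_cohort(simulate_registry(zero_noise_config(400, seed = 6)))
  with_codes <- s$coding[s$coding$true_cause != "other", ]
  expect_true(all(with_codes$p_correct_procedure == 1))
  expect_true(all(s$noise$n_contacts == 0) || nrow(s$noise) == 0)
})

test_that("every true reoperation has a contact inside the follow-up window", {
  cohort <- simulate_registry(registry_config(n_fractures = 500, seed = 14))
  reops <- cohort$draws[cohort$draws$true_cause != "not_reoperation", ]
  expect_true(all(!is.na(reops$reop_day)))
  expect_true(all(reops$reop_day >= 1 & reops$reop_day <= 365))
  has_contact <- reops$fracture_id %in% cohort$contacts_log$fracture_id
  expect_true(all(has_contact))

  # cause-specific admissible day windows
  d <- cohort$draws
  expect_true(all(d$reop_day[d$true_cause == "re_osteosynthesis"] <= 42))
  expect_true(all(d$reop_day[d$true_cause == "secondary_arthroplasty"] > 42))
  expect_true(all(d$reop_day[d$true_cause == "hardware_removal"] >= 42))
})

test_that("false positives for named causes arise only through the decoy overlap", {
  clean <- simulate_registry(registry_config(n_fractures = 1500, seed = 15,
                                             decoy_overlap = 0))
  fr <- classify_cohort(clean$events, clean$index)
  ev <- evaluate_causes(fr, clean$gold)
  named <- setdiff(cause_levels(), c("other", "not_reoperation"))
  expect_true(all(ev$fp[ev$target %in% named] == 0))

  noisy <- simulate_registry(registry_config(n_fractures = 1500, seed = 15,
                                             decoy_overlap = 0.5))
  fr2 <- classify_cohort(noisy$events, noisy$index)
  ev2 <- evaluate_causes(fr2, noisy$gold)
  expect_gt(sum(ev2$fp[ev2$target %in% named]), 0)
})

test_that("a second lower-severity reoperation never changes the fracture label", {
  cohort <- simulate_registry(registry_config(n_fractures = 1200, seed = 16,
                                              p_second_reop = 0.5))
  second <- unique(cohort$contacts_log$fracture_id[
    cohort$contacts_log$source == "second_reop_hardware_removal"
  ])
  expect_gt(length(second), 0)
  fr <- classify_cohort(cohort$events, cohort$index)
  gold <- cohort$gold
  majors <- gold$fracture_id[gold$true_cause %in%
                               c("infection", "nonunion", "re_osteosynthesis",
                                 "secondary_arthroplasty")]
  # fractures whose major cause was coded AND that got a second contact
  # still roll up to the major cause, not hardware removal
  labelled <- fr$cause[fr$fracture_id %in% intersect(second, majors)]
  expect_false(any(labelled == "not_reoperation"))
  expect_true(all(labelled %in% c("infection", "nonunion", "re_osteosynthesis",
                                  "secondary_arthroplasty", "hardware_removal",
                                  "other")))

  # and with perfect coding the roll-up is exactly the major cause
  perfect <- zero_noise_config(600, seed = 17)
  perfect$p_second_reop <- 0.5
  cohort2 <- simulate_registry(perfect)
  fr2 <- classify_cohort(cohort2$events, cohort2$index)
  joined <- dplyr::inner_join(fr2, cohort2$gold, by = "fracture_id")
  expect_identical(joined$cause, joined$true_cause)
})

test_that("censoring truncates follow-up and relabels lost reoperations", {
  cohort <- simulate_registry(registry_config(n_fractures = 800, seed = 18,
                                              censoring_rate = 0.3))
  d <- cohort$draws
  cens <- d[!is.na(d$censored_at), ]
  expect_gt(nrow(cens), 0)
  # no contact after a fracture's censoring day
  log <- dplyr::inner_join(cohort$contacts_log,
                           cens[, c("fracture_id", "censored_at")],
                           by = "fracture_id")
  expect_true(all(log$day <= log$censored_at))
  # gold label of censored-before-reoperation fractures is not_reoperation
  lost <- cens[!is.na(cens$reop_day) & cens$reop_day > cens$censored_at, ]
  gold_lost <- cohort$gold$true_cause[match(lost$fracture_id,
                                            cohort$gold$fracture_id)]
  expect_true(all(gold_lost == "not_reoperation"))
})

test_that("summaries report per-cause counts, coding rates and noise", {
  cohort <- simulate_registry(registry_config(n_fractures = 500, seed = 19))
  s <- summarize_cohort(cohort)
  expect_equal(sum(s$causes$n_fractures), 500)
  expect_equal(sum(s$causes$prevalence), 1)
  expect_true(all(c("p_correct_procedure", "p_correct_diagnosis", "p_both")
                  %in% names(s$coding)))
})
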