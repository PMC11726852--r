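# Build a firing table directly: each pattern group is characterized by
# its firing rates in gold-positive and gold-negative fractures.
make_fires <- function(gold, rates) {
  out <- tibble::tibble(fracture_id = sprintf("F%04d", seq_along(gold)))
  for (name in names(rates)) {
    r <- rates[[name]]
    out[[name]] <- ifelse(gold, runif(length(gold)) < r[1],
                          runif(length(gold)) < r[2])
  }
  out
}

test_that("pattern ranking follows univariate association with the gold label", {
  set.seed(101)
  gold <- rep(c(TRUE, FALSE), c(150, 850))
  fires <- make_fires(gold, list(
    a_strong = c(0.90, 0.01),
    b_weak = c(0.10, 0.05),
    c_never = c(0, 0)
  ))
  ranked <- rank_patterns(fires, gold)
  expect_identical(ranked$pattern, c("a_strong", "b_weak", "c_never"))
  expect_equal(ranked$score[3], 0)   # never fires: zero score, ranked last

  # complete separation (fires only in positives) ranks first, deterministically
  fires$sep <- gold & c(rep(TRUE, 40), rep(FALSE, length(gold) - 40))
  ranked2 <- rank_patterns(fires, gold)
  expect_identical(ranked2$pattern[1], "a_strong")
  expect_true(all(is.finite(ranked2$score)))
  expect_identical(ranked2, rank_patterns(fires, gold))  # stable under re-evaluation
})

test_that("ranking recovers the generative informativeness order", {
  set.seed(202)
  gold <- runif(500) < 0.3
  fires <- make_fires(gold, list(
    top = c(0.85, 0.02), mid = c(0.50, 0.05), low = c(0.20, 0.10),
    noise = c(0.05, 0.05)
  ))
  expect_identical(rank_patterns(fires, gold)$pattern,
                   c("top", "mid", "low", "noise"))
})

test_that("stepwise traces have non-decreasing sensitivity and test-positives", {
  set.seed(303)
  for (i in 1:5) {
    gold <- runif(400) < runif(1, 0.1, 0.4)
    rates <- lapply(1:6, function(j) c(runif(1), runif(1, 0, 0.3)))
    names(rates) <- paste0("g", 1:6)
    fires <- make_fires(gold, rates)
    trace <- build_stepwise(fires, gold)
    s <- trace$steps
    expect_true(all(diff(s$sensitivity) >= 0))
    expect_true(all(diff(s$tp + s$fp) >= 0))
    expect_equal(which.max(s$kappa), trace$selected_step)
  }
})

test_that("a perfectly predictive pattern is selected at step one with kappa 1", {
  gold <- rep(c(TRUE, FALSE), c(30, 70))
  fires <- tibble::tibble(perfect = gold, junk = rep(c(TRUE, FALSE), 50))
  trace <- build_stepwise(fires, gold)
  expect_equal(trace$selected_step, 1)
  expect_identical(trace$order[1], "perfect")
  expect_equal(trace$steps$kappa[1], 1)
  expect_error(build_stepwise(fires, gold, max_steps = 0), "max_steps")
})

test_that("a pattern firing only in negatives lowers PPV and kappa; earlier step stays selected", {
  gold <- rep(c(TRUE, FALSE), c(40, 160))
  fires <- tibble::tibble(
    good = gold,
    bad = !gold & seq_along(gold) <= 80   # fires in 40 negatives only
  )
  trace <- build_stepwise(fires, gold, order = c("good", "bad"))
  s <- trace$steps
  expect_lt(s$ppv[2], s$ppv[1])
  expect_equal(s$sensitivity[2], s$sensitivity[1])
  expect_lt(s$kappa[2], s$kappa[1])
  expect_equal(trace$selected_step, 1)
})

test_that("kappa-argmax selection matches exhaustive evaluation of cumulative unions", {
  set.seed(404)
  for (i in 1:8) {
    n_pat <- sample(3:12, 1)
    gold <- runif(300) < 0.25
    rates <- lapply(seq_len(n_pat), function(j) c(runif(1), runif(1, 0, 0.5)))
    names(rates) <- paste0("p", seq_len(n_pat))
    fires <- make_fires(gold, rates)
    order <- rank_patterns(fires, gold)$pattern
    trace <- build_stepwise(fires, gold)

    # oracle: evaluate every cumulative union directly with independent kappa
    kappas <- vapply(seq_along(order), function(k) {
      pred <- Reduce(`|`, lapply(order[seq_len(k)], function(nm) fires[[nm]]))
      oracle_kappa(sum(pred & gold), sum(pred & !gold),
                   sum(!pred & gold), sum(!pred & !gold))
    }, numeric(1))
    expect_equal(trace$selected_step, which.max(kappas))
    expect_equal(trace$steps$kappa, kappas, tolerance = 1e-12)
  }
})

test_that("ties in kappa select the smallest step", {
  gold <- rep(c(TRUE, FALSE), c(20, 80))
  # duplicated pattern: step 2 adds nothing, kappa identical
  fires <- tibble::tibble(a = gold, b = gold)
  trace <- build_stepwise(fires, gold, order = c("a", "b"))
  expect_equal(trace$steps$kappa[1], trace$steps$kappa[2])
  expect_equal(trace$selected_step, 1)
})

test_that("composites fire when any constituent selected step fires", {
  set.seed(505)
  gold_a <- rep(c(TRUE, FALSE), c(25, 175))
  gold_b <- rep(c(FALSE, TRUE, FALSE), c(25, 30, 145))  # disjoint positives
  fires_a <- tibble::tibble(pa = gold_a)
  fires_b <- tibble::tibble(pb = gold_b)
  tr_a <- build_stepwise(fires_a, gold_a)
  tr_b <- build_stepwise(fires_b, gold_b)
  comp <- combine_composite(list(tr_a, tr_b), gold_a | gold_b)
  # disjoint firing sets: composite tp is the sum of constituent tps
  expect_equal(comp$counts$tp,
               tr_a$steps$tp[tr_a$selected_step] + tr_b$steps$tp[tr_b$selected_step])
  # union monotonicity: composite sensitivity >= each constituent's
  expect_gte(sensitivity(comp$counts), 100 * mean((gold_a & fires_a$pa)[gold_a]))
})

test_that("step traces tidy, glance and plot", {
  gold <- rep(c(TRUE, FALSE), c(30, 70))
  fires <- tibble::tibble(a = gold, b = gold | seq_along(gold) <= 50)
  trace <- build_stepwise(fires, gold)
  td <- tidy(trace)
  expect_s3_class(td, "tbl_df")
  expect_true(sum(td$selected) == 1)
  gl <- glance(trace)
  expect_equal(gl$step, trace$selected_step)
  p <- ggplot2::autoplot(trace)
  expect_s3_class(p, "ggplot")
})

test_that("pattern firing respects group-level day windows", {
  index <- make_index()
  events <- dplyr::bind_rows(
    make_contact(index, 30, "KNGC25"),
    make_contact(make_index(fracture_id = "F2"), 100, "KNGC25", row = 1)
  )
  index2 <- dplyr::bind_rows(index, make_index(fracture_id = "F2"))
  cand <- find_reoperations(events, index2)
  groups <- list(
    early = list(patterns = code_pattern("KNxC"), window = c(1, 42)),
    late = list(patterns = code_pattern("KNxC"), window = c(43, 365))
  )
  fires <- pattern_fires(cand, index2, groups)
  expect_identical(fires$early, c(TRUE, FALSE))
  expect_identical(fires$late, c(FALSE, TRUE))
})
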