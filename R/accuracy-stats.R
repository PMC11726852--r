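#' Diagnostic accuracy statistics
#'
#' Validation statistics for a binary phenotyping rule against a gold
#' standard: the 2x2 confusion table, sensitivity, positive predictive
#' value, specificity, negative predictive value (all as percentages
#' with exact Clopper-Pearson intervals), Cohen's kappa, and the AUC of
#' a single deployed binary rule, which equals balanced accuracy
#' (mean of sensitivity and specificity as fractions). Undefined metrics
#' (zero denominators) propagate as `NA`, never as 0 or an error.
#'
#' @name accuracy-stats
NULL

#' Build a confusion table
#'
#' @param predicted logical vector: rule-positive.
#' @param gold logical vector: gold-standard-positive, same length and
#'   order (i.e. already aligned on fracture ids).
#' @return a `reop_confusion` tibble row with columns `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_counts <- function(predicted, gold) {
  stopifnot(length(predicted) == length(gold),
            is.logical(predicted), is.logical(gold),
            !anyNA(predicted), !anyNA(gold))
  new_confusion(
    tp = sum(predicted & gold), fp = sum(predicted & !gold),
    fn = sum(!predicted & gold), tn = sum(!predicted & !gold)
  )
}

#' @rdname confusion_counts
#' @param tp,fp,fn,tn the four cells (non-negative, positive total).
#' @export
new_confusion <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(cells >= 0), sum(cells) > 0)
  out <- tibble::tibble(tp = as.integer(tp), fp = as.integer(fp),
                        fn = as.integer(fn), tn = as.integer(tn))
  class(out) <- c("reop_confusion", class(out))
  out
}

#' Reconstruct confusion cells from marginal counts
#'
#' Validation reports often print the test-positive and test-negative
#' marginals (`TP`, `TN`) alongside the correctly classified diagonal
#' (`TrP` true positives, `TrN` true negatives) rather than the four
#' cells. The cells follow as tp = TrP, fp = TP - TrP, fn = TN - TrN,
#' tn = TrN.
#'
#' @param test_pos all rule-positives (marginal).
#' @param true_pos correctly classified positives (diagonal).
#' @param test_neg all rule-negatives (marginal).
#' @param true_neg correctly classified negatives (diagonal).
#' @return `reop_confusion` row.
#' @export
confusion_from_marginals <- function(test_pos, true_pos, test_neg, true_neg) {
  if (true_pos > test_pos || true_neg > test_neg) {
    stop("Diagonal counts cannot exceed their marginals", call. = FALSE)
  }
  new_confusion(tp = true_pos, fp = test_pos - true_pos,
                fn = test_neg - true_neg, tn = true_neg)
}

pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

#' Accuracy metrics from confusion cells
#'
#' `sensitivity()` is 100*tp/(tp+fn); `ppv()` is 100*tp/(tp+fp);
#' `specificity()` 100*tn/(tn+fp); `npv()` 100*tn/(tn+fn). All return
#' percentages, `NA` when the denominator is zero.
#'
#' @param counts a `reop_confusion` row (or anything with `tp`, `fp`,
#'   `fn`, `tn` fields).
#' @return numeric percent.
#' @export
sensitivity <- function(counts) pct(counts$tp, counts$tp + counts$fn)

#' @rdname sensitivity
#' @export
ppv <- function(counts) pct(counts$tp, counts$tp + counts$fp)

#' @rdname sensitivity
#' @export
specificity <- function(counts) pct(counts$tn, counts$tn + counts$fp)

#' @rdname sensitivity
#' @export
npv <- function(counts) pct(counts$tn, counts$tn + counts$fn)

#' Exact Clopper-Pearson binomial interval
#'
#' Exact interval for a binomial proportion via the beta-quantile
#' characterization: with `x` successes in `n` trials at level
#' `1 - alpha`, the lower bound is the `alpha/2` quantile of
#' Beta(x, n - x + 1) (0 when x = 0) and the upper bound the
#' `1 - alpha/2` quantile of Beta(x + 1, n - x) (1 when x = n). Equals
#' inversion of the exact binomial test at `alpha/2` per tail.
#'
#' @param x number of successes, `0 <= x <= n` (vectorized).
#' @param n number of trials, `n >= 1`.
#' @param level confidence level, default 0.95.
#' @return tibble with `estimate`, `lower`, `upper` (percent) and
#'   `level`.
#' @examples
#' clopper_pearson(88, 114)  # 77.2 (68.4-84.5)
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(all(x >= 0), all(x <= n), all(n >= 1), level > 0, level < 1)
  alpha <- 1 - level
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  tibble::tibble(
    estimate = 100 * x / n, lower = 100 * lower, upper = 100 * upper,
    level = level
  )
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement: kappa = (po - pe)/(1 - pe) with observed
#' agreement po = (tp+tn)/N and chance agreement pe computed from the
#' row/column marginals. Returns 1 for perfect agreement even when
#' pe = 1 (a degenerate all-one-class table).
#'
#' @inheritParams sensitivity
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  po <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  if (pe == 1) return(if (po == 1) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

#' AUC of a single binary rule
#'
#' A deployed rule yields one point on the ROC plane; the area under
#' the two-segment curve through it is (sensitivity + specificity)/2 on
#' the fraction scale, i.e. balanced accuracy.
#'
#' @inheritParams sensitivity
#' @return AUC in `[0, 1]`, `NA` if either class is empty.
#' @export
binary_auc <- function(counts) {
  se <- sensitivity(counts)
  sp <- specificity(counts)
  if (is.na(se) || is.na(sp)) return(NA_real_)
  (se / 100 + sp / 100) / 2
}

#' One-year cumulative incidence
#'
#' @param cases event count during follow-up.
#' @param at_risk size of the population at risk.
#' @return percent.
#' @export
cumulative_incidence <- function(cases, at_risk) {
  stopifnot(at_risk > 0)
  100 * cases / at_risk
}

#' Full accuracy report for one rule
#'
#' Bundles the four proportion metrics with exact Clopper-Pearson
#' intervals, Cohen's kappa, the binary-rule AUC, and the underlying
#' cells into a `reop_accuracy` object with [tidy()]/[glance()]
#' methods.
#'
#' @inheritParams sensitivity
#' @param level confidence level for the intervals.
#' @return `reop_accuracy` object.
#' @export
accuracy_report <- function(counts, level = 0.95) {
  ci_of <- function(num, den) {
    if (den == 0) {
      tibble::tibble(estimate = NA_real_, lower = NA_real_,
                     upper = NA_real_, level = level)
    } else {
      clopper_pearson(num, den, level)
    }
  }
  metrics <- dplyr::bind_rows(
    sensitivity = ci_of(counts$tp, counts$tp + counts$fn),
    ppv = ci_of(counts$tp, counts$tp + counts$fp),
    specificity = ci_of(counts$tn, counts$tn + counts$fp),
    npv = ci_of(counts$tn, counts$tn + counts$fn),
    .id = "metric"
  )
  structure(
    list(counts = counts, metrics = metrics,
         kappa = cohen_kappa(counts), auc = binary_auc(counts),
         level = level),
    class = "reop_accuracy"
  )
}

#' @export
print.reop_accuracy <- function(x, ...) {
  cat("Diagnostic accuracy (n = ",
      with(x$counts, tp + fp + fn + tn), ")\n", sep = "")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %5.1f%% (%.0f%% CI %.1f-%.1f)\n", m$metric[i],
                m$estimate[i], 100 * x$level, m$lower[i], m$upper[i]))
  }
  cat(sprintf("  kappa %.2f, AUC %.2f\n", x$kappa, x$auc))
  cat(sprintf("  cells: tp %d, fp %d, fn %d, tn %d\n",
              x$counts$tp, x$counts$fp, x$counts$fn, x$counts$tn))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an accuracy report
#'
#' @param x `reop_accuracy` object.
#' @param ... unused.
#' @return tibble with one row per proportion metric (`estimate`,
#'   `lower`, `upper` in percent) plus rows for `kappa` and `auc` on
#'   their natural scales.
#' @export
tidy.reop_accuracy <- function(x, ...) {
  dplyr::bind_rows(
    x$metrics[, c("metric", "estimate", "lower", "upper")],
    tibble::tibble(metric = c("kappa", "auc"),
                   estimate = c(x$kappa, x$auc),
                   lower = NA_real_, upper = NA_real_)
  )
}

#' @rdname tidy.reop_accuracy
#' @return `glance()`: a one-row tibble with all metrics and cells.
#' @export
glance.reop_accuracy <- function(x, ...) {
  m <- x$metrics
  g <- function(metric, col) m[[col]][m$metric == metric]
  tibble::tibble(
    sensitivity = g("sensitivity", "estimate"),
    sensitivity_lower = g("sensitivity", "lower"),
    sensitivity_upper = g("sensitivity", "upper"),
    ppv = g("ppv", "estimate"), ppv_lower = g("ppv", "lower"),
    ppv_upper = g("ppv", "upper"),
    specificity = g("specificity", "estimate"), npv = g("npv", "estimate"),
    kappa = x$kappa, auc = x$auc,
    tp = x$counts$tp, fp = x$counts$fp, fn = x$counts$fn, tn = x$counts$tn,
    n = x$counts$tp + x$counts$fp + x$counts$fn + x$counts$tn
  )
}

#' Evaluate per-cause rules against gold labels
#'
#' For each cause (and the major/minor composites and overall
#' any-reoperation rule) cross-tabulates fracture-level predictions
#' against gold labels and produces a validation-table-shaped tibble:
#' one row per target with sensitivity (CI), PPV (CI), specificity,
#' NPV, kappa, AUC, and the four cells.
#'
#' @param predicted fracture-level tibble from [summarize_fractures()]
#'   (needs `fracture_id`, `cause`, `composite`).
#' @param gold gold-label tibble (`fracture_id`, `true_cause`).
#' @param level confidence level.
#' @return tibble with one row per target (`target` column), metrics as
#'   in [glance.reop_accuracy()].
#' @export
evaluate_causes <- function(predicted, gold, level = 0.95) {
  joined <- dplyr::inner_join(
    predicted |> dplyr::select("fracture_id", "cause", "composite"),
    gold |> dplyr::select("fracture_id", "true_cause"),
    by = "fracture_id"
  )
  if (nrow(joined) != nrow(gold) || nrow(joined) != nrow(predicted)) {
    stop("Predictions and gold labels must cover the same fracture ids",
         call. = FALSE)
  }
  gold_comp <- composite_label(joined$true_cause)
  targets <- list(
    any_reoperation = list(pred = joined$cause != "not_reoperation",
                           gold = joined$true_cause != "not_reoperation"),
    major = list(pred = joined$composite == "major", gold = gold_comp == "major"),
    minor = list(pred = joined$composite == "minor", gold = gold_comp == "minor")
  )
  for (cause in setdiff(cause_levels(), "not_reoperation")) {
    targets[[cause]] <- list(pred = joined$cause == cause,
                             gold = joined$true_cause == cause)
  }
  purrr::imap(targets, function(t, name) {
    rep <- accuracy_report(confusion_counts(t$pred, t$gold), level)
    dplyr::bind_cols(tibble::tibble(target = name), glance(rep))
  }) |>
    dplyr::bind_rows()
}

#' Write an evaluation table
#'
#' @param evaluation tibble from [evaluate_causes()].
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @export
write_evaluation <- function(evaluation, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(evaluation, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    readr::write_csv(evaluation, path, progress = FALSE)
  }
  invisible(path)
}
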