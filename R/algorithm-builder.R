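#' Stepwise algorithm construction
#'
#' Code-set algorithms are built step by step: candidate code-pattern
#' groups are ranked by their univariate association with the gold
#' label, then composed cumulatively with "or" — step k classifies a
#' fracture positive when any of the top-k groups fires. Each step is
#' scored with a full accuracy report against the gold standard, and
#' the deployed step is the one with the highest Cohen's kappa (first
#' occurrence on ties, favouring parsimony). Adding codes can only add
#' positives, so sensitivity is non-decreasing across steps while PPV
#' typically falls — the trade-off the kappa-maximal step balances.
#'
#' @name algorithm-builder
NULL

#' Per-fracture pattern firing table
#'
#' For each fracture in `index` and each pattern group, records whether
#' any retained candidate reoperation of that fracture carries a
#' matching code (within the group's day window, when one is set).
#'
#' @param candidates candidate tibble ([find_reoperations()]); if an
#'   `excluded` column is present, excluded candidates are ignored.
#' @param index index-surgery tibble (fracture universe).
#' @param groups named list of pattern groups: each element either a
#'   pattern tibble ([code_pattern()]) or a list with elements
#'   `patterns` and optional `window = c(first_day, last_day)`.
#' @return tibble with `fracture_id` and one logical column per group.
#' @export
pattern_fires <- function(candidates, index, groups) {
  stopifnot(length(groups) > 0, !is.null(names(groups)))
  if ("excluded" %in% names(candidates)) {
    candidates <- dplyr::filter(candidates, !.data$excluded)
  }
  codes <- purrr::map2(candidates$procedure_codes, candidates$diagnosis_codes, c)
  out <- index |> dplyr::distinct(.data$fracture_id)
  for (name in names(groups)) {
    g <- groups[[name]]
    if (is.data.frame(g)) g <- list(patterns = g)
    w <- g$window %||% c(1, Inf)
    hit <- match_rows(codes, g$patterns) &
      candidates$days_since_index >= w[1] & candidates$days_since_index <= w[2]
    fired <- unique(candidates$fracture_id[hit])
    out[[name]] <- out$fracture_id %in% fired
  }
  out
}

# Likelihood-ratio statistic of the single-predictor logistic model
# (binary predictor => closed form from the 2x2 table; exact even under
# complete separation, where an iterative fit would only approach it).
logistic_lr <- function(fires, gold) {
  xlogx <- function(n, d) ifelse(n == 0, 0, n * log(n / d))
  a <- sum(fires & gold); b <- sum(fires & !gold)
  c_ <- sum(!fires & gold); d_ <- sum(!fires & !gold)
  n <- a + b + c_ + d_
  ll1 <- xlogx(a, a + b) + xlogx(b, a + b) + xlogx(c_, c_ + d_) + xlogx(d_, c_ + d_)
  ll0 <- xlogx(a + c_, n) + xlogx(b + d_, n)
  2 * (ll1 - ll0)
}

#' Rank candidate pattern groups
#'
#' Scores each group by the likelihood-ratio statistic of the
#' univariate logistic regression of the gold label on "group fires",
#' signed by the direction of association; groups firing in no fracture
#' score zero and sort last. Ties break by higher PPV, then by group
#' name.
#'
#' @param fires firing table from [pattern_fires()] (logical columns;
#'   a `fracture_id` column is ignored).
#' @param gold logical vector of gold positives, aligned with the rows
#'   of `fires`.
#' @return tibble ordered by decreasing score: `pattern`, `score`,
#'   `ppv`, `n_fires`.
#' @export
rank_patterns <- function(fires, gold) {
  cols <- setdiff(names(fires), "fracture_id")
  stopifnot(length(cols) > 0, nrow(fires) == length(gold),
            any(gold), any(!gold))
  scored <- purrr::map(cols, function(nm) {
    f <- fires[[nm]]
    score <- if (!any(f)) 0 else {
      lr <- logistic_lr(f, gold)
      if (mean(gold[f]) >= mean(gold)) lr else -lr
    }
    tibble::tibble(pattern = nm, score = score,
                   ppv = if (any(f)) 100 * mean(gold[f]) else NA_real_,
                   n_fires = sum(f))
  }) |>
    dplyr::bind_rows()
  scored |>
    dplyr::arrange(dplyr::desc(.data$score),
                   dplyr::desc(dplyr::coalesce(.data$ppv, -Inf)),
                   .data$pattern)
}

#' Build and score a stepwise "or" algorithm
#'
#' @param fires firing table from [pattern_fires()].
#' @param gold logical gold vector aligned with `fires` rows.
#' @param order character vector giving the step order of the groups;
#'   default ranks them with [rank_patterns()].
#' @param max_steps number of steps to build (default: all groups).
#' @param level confidence level for interval estimates.
#' @return a `reop_steptrace`: per-step accuracy table, the
#'   kappa-maximal `selected_step`, and the selected step's per-fracture
#'   predictions.
#' @export
build_stepwise <- function(fires, gold, order = NULL, max_steps = NULL,
                           level = 0.95) {
  cols <- setdiff(names(fires), "fracture_id")
  order <- order %||% rank_patterns(fires, gold)$pattern
  stopifnot(all(order %in% cols))
  max_steps <- max_steps %||% length(order)
  if (max_steps < 1) stop("max_steps must be >= 1", call. = FALSE)
  order <- order[seq_len(min(max_steps, length(order)))]

  cum <- rep(FALSE, nrow(fires))
  rows <- vector("list", length(order))
  preds <- vector("list", length(order))
  for (k in seq_along(order)) {
    cum <- cum | fires[[order[k]]]
    preds[[k]] <- cum
    rep_k <- accuracy_report(confusion_counts(cum, gold), level)
    rows[[k]] <- dplyr::bind_cols(
      tibble::tibble(step = k, pattern_added = order[k]),
      glance(rep_k)
    )
  }
  steps <- dplyr::bind_rows(rows)
  selected <- which.max(steps$kappa)
  structure(
    list(steps = steps, selected_step = selected,
         order = order,
         fracture_id = fires[["fracture_id"]],
         selected_pred = preds[[selected]],
         gold = gold, level = level),
    class = "reop_steptrace"
  )
}

#' @export
print.reop_steptrace <- function(x, ...) {
  cat("Stepwise code-set algorithm (", nrow(x$steps), " steps, selected step ",
      x$selected_step, ")\n", sep = "")
  s <- x$steps
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s step %d + %-34s sens %5.1f  ppv %5.1f  kappa %.3f\n",
                if (i == x$selected_step) "*" else " ",
                s$step[i], s$pattern_added[i],
                s$sensitivity[i], s$ppv[i], s$kappa[i]))
  }
  invisible(x)
}

#' Tidy / glance a step trace
#'
#' @param x `reop_steptrace` object.
#' @param ... unused.
#' @return `tidy()`: the per-step accuracy tibble with a `selected`
#'   flag. `glance()`: the selected step's one-row summary.
#' @export
tidy.reop_steptrace <- function(x, ...) {
  dplyr::mutate(x$steps, selected = .data$step == x$selected_step)
}

#' @rdname tidy.reop_steptrace
#' @export
glance.reop_steptrace <- function(x, ...) {
  dplyr::mutate(x$steps[x$selected_step, ],
                n_steps = nrow(x$steps), selected_step = x$selected_step)
}

#' Combine selected-step algorithms into a composite rule
#'
#' The composite (e.g. any major reoperation) classifies a fracture
#' positive when any constituent cause's selected-step algorithm fires,
#' and is scored against the composite gold label.
#'
#' @param traces list of `reop_steptrace` objects for the constituent
#'   causes (their predictions must be aligned on the same fractures).
#' @param gold logical composite gold vector.
#' @param level confidence level.
#' @return `reop_accuracy` report for the composite rule.
#' @export
combine_composite <- function(traces, gold, level = 0.95) {
  stopifnot(length(traces) > 0)
  preds <- purrr::map(traces, "selected_pred")
  stopifnot(all(lengths(preds) == length(gold)))
  combined <- purrr::reduce(preds, `|`)
  accuracy_report(confusion_counts(combined, gold), level)
}

#' Write a step-trace report
#'
#' One row per step with the full metric set, shaped like a
#' supplementary step table.
#'
#' @param trace `reop_steptrace`.
#' @param path output path (`.json` or CSV).
#' @export
write_step_trace <- function(trace, path) {
  write_evaluation(tidy(trace), path)
}

#' Plot the stepwise sensitivity/PPV trade-off
#'
#' @param object `reop_steptrace`.
#' @param ... unused.
#' @return a ggplot: sensitivity, PPV and kappa (as percent) against
#'   step number, the selected step marked.
#' @export
autoplot.reop_steptrace <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::transmute(
      .data$step, .data$selected,
      Sensitivity = .data$sensitivity, PPV = .data$ppv,
      `Kappa (x100)` = 100 * .data$kappa
    ) |>
    tidyr::pivot_longer(-c("step", "selected"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_step, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = unique(d$step)) +
    ggplot2::labs(x = "Step (cumulative \"or\" over ranked code groups)",
                  y = "Percent", colour = NULL,
                  title = "Stepwise algorithm: sensitivity rises, PPV falls",
                  subtitle = paste0("Dashed line: kappa-maximal step ",
                                    object$selected_step)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
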