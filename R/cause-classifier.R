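#' Classify candidate reoperations by cause
#'
#' Each retained candidate gets exactly one cause label. Causes are
#' evaluated in descending severity order and the first rule that fires
#' wins: infection, then nonunion, then early re-osteosynthesis (revision
#' fixation or prosthetic conversion within 42 days of the index),
#' secondary arthroplasty (prosthesis after day 42), hardware removal
#' (implant-removal codes from day 42 on), wound treatment (skin-chapter
#' surgery without infection evidence — the precedence order itself
#' enforces "unrelated to an infection"), and `other` as the total
#' fallback. Because a single 42-day cut separates the early-revision
#' and prosthetic rules, no candidate can be both.
#'
#' @param candidates candidate tibble from [find_reoperations()],
#'   optionally after [apply_exclusions()]; excluded candidates are
#'   labelled `not_reoperation`.
#' @param config code-set configuration; each cause's deployed rule is
#'   the "or"-union of its pattern groups up to `selected_step`,
#'   constrained to the cause's day window.
#' @return `candidates` with a `cause` column and one logical
#'   `fired_<cause>` column per configured cause.
#' @export
classify_reoperations <- function(candidates, config = default_code_config()) {
  validate_code_config(config)
  n <- nrow(candidates)
  causes <- intersect(cause_levels(), names(config$causes))
  excluded <- if ("excluded" %in% names(candidates)) candidates$excluded else rep(FALSE, n)
  all_codes <- purrr::map2(candidates$procedure_codes, candidates$diagnosis_codes, c)

  fired <- matrix(FALSE, nrow = n, ncol = length(causes),
                  dimnames = list(NULL, causes))
  for (cause in causes) {
    pats <- cause_patterns(config, cause)
    w <- config$causes[[cause]]$window %||% c(1, Inf)
    in_window <- candidates$days_since_index >= w[1] &
      candidates$days_since_index <= w[2]
    hit <- match_rows(all_codes, pats)
    fired[, cause] <- !excluded & in_window & hit
  }

  label <- rep("other", n)
  for (cause in rev(causes)) label[fired[, cause]] <- cause
  label[excluded] <- "not_reoperation"

  out <- dplyr::mutate(candidates, cause = label)
  for (cause in causes) out[[paste0("fired_", cause)]] <- fired[, cause]
  out
}

#' Roll classified candidates up to fracture level
#'
#' One output row per index fracture: the most severe cause among its
#' candidate reoperations (severity order: infection, nonunion,
#' re-osteosynthesis, secondary arthroplasty, hardware removal, wound
#' treatment, other), its major/minor composite, the day of the first
#' retained reoperation, and per-cause fired flags aggregated with any().
#' Fractures with no retained candidate are `not_reoperation`.
#'
#' @param classified output of [classify_reoperations()].
#' @param index index-surgery tibble; defines the fracture universe.
#' @return tibble, one row per fracture: `fracture_id`, `cause`,
#'   `composite`, `first_reop_day`, `n_reoperations`, fired flags.
#' @export
summarize_fractures <- function(classified, index) {
  fired_cols <- grep("^fired_", names(classified), value = TRUE)
  retained <- classified |>
    dplyr::filter(.data$cause != "not_reoperation")
  per_fracture <- retained |>
    dplyr::group_by(.data$fracture_id) |>
    dplyr::summarise(
      cause = worst_cause(.data$cause),
      first_reop_day = min(.data$days_since_index),
      n_reoperations = dplyr::n(),
      dplyr::across(dplyr::all_of(fired_cols), any),
      .groups = "drop"
    )
  index |>
    dplyr::distinct(.data$fracture_id) |>
    dplyr::left_join(per_fracture, by = "fracture_id") |>
    dplyr::mutate(
      cause = dplyr::coalesce(.data$cause, "not_reoperation"),
      n_reoperations = dplyr::coalesce(.data$n_reoperations, 0L),
      composite = composite_label(.data$cause),
      dplyr::across(dplyr::all_of(fired_cols), \(x) dplyr::coalesce(x, FALSE))
    ) |>
    dplyr::relocate("composite", .after = "cause")
}

#' Run the full identification + classification pipeline
#'
#' Convenience wrapper: [find_reoperations()], [apply_exclusions()],
#' [classify_reoperations()], [summarize_fractures()].
#'
#' @inheritParams find_reoperations
#' @inheritParams classify_reoperations
#' @return fracture-level tibble from [summarize_fractures()].
#' @export
classify_cohort <- function(events, index, config = default_code_config(),
                            window_days = 365) {
  find_reoperations(events, index, window_days,
                    chapter_regions = config$chapter_regions %||% "positional") |>
    apply_exclusions(config) |>
    classify_reoperations(config) |>
    summarize_fractures(index)
}
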