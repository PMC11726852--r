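#' Identify candidate reoperations
#'
#' A candidate reoperation is a hospital contact that (i) carries at
#' least one surgical procedure code in the nervous-system (KA),
#' musculoskeletal (KN) or skin (KQ) chapter, (ii) falls within the
#' follow-up window, day 1 to `window_days` after the index surgery
#' (same-day codes belong to the index contact and never self-match),
#' (iii) lies in the same anatomical area as the index surgery
#' (region-neutral procedure codes pass for any region), and (iv) is
#' laterality-compatible with the index side — the same side, or either
#' side unspecified.
#'
#' @param events event tibble as returned by [read_events()] or
#'   [simulate_registry()]; may contain many patients.
#' @param index index-surgery tibble ([read_index_surgeries()]); one row
#'   per fracture.
#' @param window_days length of follow-up in days (default 365).
#' @param chapter_regions passed to [code_region()].
#' @return tibble of candidates, one row per qualifying contact per
#'   fracture: `fracture_id`, `patient_id`, `contact_id`, `reop_date`,
#'   `days_since_index`, `laterality`, and list-columns
#'   `procedure_codes`, `diagnosis_codes`.
#' @export
find_reoperations <- function(events, index, window_days = 365,
                              chapter_regions = "positional") {
  stopifnot(window_days >= 1)
  if (nrow(events) == 0 || nrow(index) == 0) return(empty_candidates())

  ev <- events |>
    dplyr::mutate(
      .chapter = substr(.data$code, 1, 2),
      .surgical = .data$kind == "procedure" & .data$.chapter %in% c("KA", "KN", "KQ"),
      .region = code_region(.data$code, chapter_regions)
    )

  joined <- dplyr::inner_join(
    ev,
    index |>
      dplyr::select("patient_id", "fracture_id", "surgery_date",
                    index_region = "region", index_side = "laterality",
                    index_procedure = "procedure"),
    by = "patient_id", relationship = "many-to-many"
  ) |>
    dplyr::mutate(days_since_index = as.integer(.data$date - .data$surgery_date)) |>
    dplyr::filter(.data$days_since_index >= 1,
                  .data$days_since_index <= window_days)
  if (nrow(joined) == 0) return(empty_candidates())

  contacts <- joined |>
    dplyr::group_by(.data$fracture_id, .data$patient_id, .data$contact_id,
                    .data$date, .data$days_since_index,
                    .data$index_region, .data$index_side) |>
    dplyr::summarise(
      has_surgical = any(.data$.surgical),
      region_ok = any(.data$.surgical &
                        (is.na(.data$.region) | .data$.region == .data$index_region[1])),
      laterality = contact_side(.data$laterality),
      procedure_codes = list(.data$code[.data$kind == "procedure"]),
      diagnosis_codes = list(.data$code[.data$kind == "diagnosis"]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$has_surgical, .data$region_ok,
                  laterality_compatible(.data$index_side, .data$laterality))

  contacts |>
    dplyr::transmute(
      .data$fracture_id, .data$patient_id, .data$contact_id,
      reop_date = .data$date, .data$days_since_index,
      .data$laterality, .data$procedure_codes, .data$diagnosis_codes
    ) |>
    dplyr::arrange(.data$fracture_id, .data$days_since_index, .data$contact_id)
}

# Side of a whole contact: the unique specified side among its coded
# events; contacts with no side, or conflicting sides, count as
# unspecified (the permissive reading used for missing side coding).
contact_side <- function(sides) {
  s <- unique(sides[sides %in% c("left", "right")])
  if (length(s) == 1) s else "unspecified"
}

empty_candidates <- function() {
  tibble::tibble(
    fracture_id = character(), patient_id = character(),
    contact_id = character(), reop_date = as.Date(character()),
    days_since_index = integer(), laterality = character(),
    procedure_codes = list(), diagnosis_codes = list()
  )
}

#' Apply reoperation exclusions
#'
#' Planned removal of K-wires or external fixation and care for chronic
#' foot ulcers, decubitus or venous disease are not reoperations. This
#' flags candidates matching the configured exclusion sets with a
#' machine-readable reason; nothing is dropped, so
#' retained + excluded = input.
#'
#' Exclusion types: `procedure_only` fires only when every qualifying
#' surgical code on the contact matches the set (a contact that also
#' performed other surgery is retained); `procedure_any` fires on any
#' matching procedure code; `diagnosis_any` fires on any matching
#' diagnosis code. When several exclusions fire, the first in
#' configuration order is reported.
#'
#' @param candidates candidate tibble from [find_reoperations()].
#' @param config code-set configuration (uses `config$exclusions`);
#'   an empty or missing exclusion list excludes nothing.
#' @return `candidates` with logical `excluded` and character
#'   `exclusion_reason` columns appended.
#' @export
apply_exclusions <- function(candidates, config = default_code_config()) {
  exclusions <- config$exclusions %||% list()
  n <- nrow(candidates)
  reason <- rep(NA_character_, n)
  surg_only <- lapply(candidates$procedure_codes, function(p) {
    p[substr(p, 1, 2) %in% c("KA", "KN", "KQ")]
  })
  for (name in names(exclusions)) {
    ex <- exclusions[[name]]
    hit <- switch(ex$type,
      procedure_only = {
        # every qualifying surgical code on the contact matches the set
        idx <- rep(seq_len(n), lengths(surg_only))
        codes <- unlist(surg_only, use.names = FALSE)
        per_code <- code_hits(codes, ex$patterns)
        n_hit <- tabulate(idx[per_code], nbins = n)
        lengths(surg_only) > 0 & n_hit == lengths(surg_only)
      },
      procedure_any = match_rows(candidates$procedure_codes, ex$patterns),
      diagnosis_any = match_rows(candidates$diagnosis_codes, ex$patterns)
    )
    reason[hit & is.na(reason)] <- name
  }
  candidates |>
    dplyr::mutate(excluded = !is.na(reason), exclusion_reason = reason)
}

#' Write the candidate table
#'
#' Flattens the code list-columns to space-separated strings so the
#' table round-trips as plain CSV.
#'
#' @param candidates candidate tibble (with or without exclusion flags).
#' @param path output path.
#' @export
write_candidates <- function(candidates, path) {
  flat <- candidates |>
    dplyr::mutate(
      procedure_codes = vapply(.data$procedure_codes, paste, character(1), collapse = " "),
      diagnosis_codes = vapply(.data$diagnosis_codes, paste, character(1), collapse = " ")
    )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}
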