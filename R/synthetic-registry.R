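#' Synthetic registry configuration
#'
#' Generates configuration for a synthetic national-registry cohort of
#' index fracture surgeries with known ground truth. Defaults emulate a
#' Danish one-year fracture cohort: the anatomical mix reproduces the
#' relative primary-surgery volumes across the seven regions, true
#' reoperation causes occur at their observed one-year cumulative
#' incidences (hardware removal 7.5%, wound treatment 5.4%,
#' re-osteosynthesis 1.7%, other 1.2%, infection 1.0%, secondary
#' arthroplasty 0.8%, nonunion 0.8%), and the coding-error model uses
#' the code-usage rates reported in national validation work — e.g. the
#' correct infection procedure codes (KNxW69/KNxW59) present in only 26%
#' of true infections, the correct diagnosis (DT846) in 33%, both in
#' 10%. When a correct code is suppressed the contact still carries a
#' plausible nonspecific surgical code from a decoy pool, so every true
#' reoperation remains identifiable as a contact even when its cause is
#' not codable.
#'
#' @param n_fractures cohort size (index fractures; one patient each).
#' @param region_mix named probabilities over the region letters `B`..`H`
#'   (normalized internally).
#' @param cause_prevalences named probabilities of each true cause; the
#'   remainder is "no reoperation". Must sum to at most 1.
#' @param coding_model per-cause list with `p_proc`, `p_diag`, `p_both`:
#'   probabilities that the reoperation contact carries the correct
#'   procedure code, the correct diagnosis code, or both
#'   (`p_both <= min(p_proc, p_diag)`).
#' @param laterality_missing_rate probability that a reoperation
#'   contact's side coding is missing.
#' @param noise_rates named per-fracture probabilities of non-reoperation
#'   contacts: `er_visit`, `new_fracture`, `chronic_wound`,
#'   `kwire_removal`, `exfix_removal`, `contralateral`.
#' @param decoy_overlap probability that a decoy procedure code is drawn
#'   from a generic revision-fixation stem (`KNxJ`) that collides with
#'   the early re-osteosynthesis patterns, instead of a neutral stem;
#'   controls the false-positive structure, which real registries do not
#'   report.
#' @param p_second_reop probability that a fracture with a major true
#'   cause also receives a later, lower-severity hardware-removal
#'   contact (exercises the severity roll-up).
#' @param censoring_rate probability that follow-up is truncated at a
#'   uniform day (death before a planned reoperation); a censored
#'   fracture whose reoperation falls after truncation becomes a true
#'   non-reoperation.
#' @param start_date first possible index-surgery date; index dates are
#'   uniform over the following year.
#' @param seed integer seed making generation reproducible.
#' @return validated `SyntheticConfig`-style list.
#' @export
registry_config <- function(n_fractures = 2347,
                            region_mix = default_region_mix(),
                            cause_prevalences = default_cause_prevalences(),
                            coding_model = default_coding_model(),
                            laterality_missing_rate = 0.3,
                            noise_rates = default_noise_rates(),
                            decoy_overlap = 0,
                            p_second_reop = 0,
                            censoring_rate = 0,
                            start_date = as.Date("2016-01-01"),
                            seed = 1L) {
  config <- list(
    n_fractures = as.integer(n_fractures), region_mix = region_mix,
    cause_prevalences = cause_prevalences, coding_model = coding_model,
    laterality_missing_rate = laterality_missing_rate,
    noise_rates = noise_rates, decoy_overlap = decoy_overlap,
    p_second_reop = p_second_reop, censoring_rate = censoring_rate,
    start_date = as.Date(start_date), seed = as.integer(seed)
  )
  validate_registry_config(config)
}

#' @rdname registry_config
#' @export
default_region_mix <- function() {
  # Primary-surgery volumes per region implied by a national one-year
  # fracture cohort (reoperation counts over region-specific
  # reoperation rates), normalized.
  v <- c(B = 1093, C = 3400, D = 886, E = 75, F = 3416, G = 909, H = 1688)
  v / sum(v)
}

#' @rdname registry_config
#' @export
default_cause_prevalences <- function() {
  c(hardware_removal = 0.075, wound_treatment = 0.054,
    re_osteosynthesis = 0.017, other = 0.012, infection = 0.010,
    secondary_arthroplasty = 0.008, nonunion = 0.008)
}

#' @rdname registry_config
#' @export
default_coding_model <- function() {
  list(
    infection = list(p_proc = 0.26, p_diag = 0.33, p_both = 0.10),
    nonunion = list(p_proc = 0.18, p_diag = 0.11, p_both = 0.08),
    re_osteosynthesis = list(p_proc = 0.99, p_diag = 0.07, p_both = 0.07),
    secondary_arthroplasty = list(p_proc = 0.03, p_diag = 0, p_both = 0),
    hardware_removal = list(p_proc = 0.99, p_diag = 0, p_both = 0),
    wound_treatment = list(p_proc = 0.99, p_diag = 0, p_both = 0),
    other = list(p_proc = 0, p_diag = 0, p_both = 0)
  )
}

#' @rdname registry_config
#' @export
default_noise_rates <- function() {
  c(er_visit = 0.009, new_fracture = 0.0016, chronic_wound = 0.0011,
    kwire_removal = 0.0064, exfix_removal = 0.001, contralateral = 0.012)
}

#' A noise-free configuration
#'
#' All correct codes always present, no noise contacts, no missing
#' laterality: the pipeline must recover the ground truth exactly on
#' cohorts generated from this.
#'
#' @inheritParams registry_config
#' @param ... passed to [registry_config()].
#' @export
zero_noise_config <- function(n_fractures = 500, seed = 1L, ...) {
  perfect <- lapply(default_coding_model(), function(m) {
    list(p_proc = 1, p_diag = 1, p_both = 1)
  })
  perfect$other <- list(p_proc = 0, p_diag = 0, p_both = 0)
  registry_config(
    n_fractures = n_fractures, coding_model = perfect,
    laterality_missing_rate = 0,
    noise_rates = c(er_visit = 0, new_fracture = 0, chronic_wound = 0,
                    kwire_removal = 0, exfix_removal = 0, contralateral = 0),
    seed = seed, ...
  )
}

#' A validation-cohort configuration
#'
#' Emulates the composition of a chart-reviewed reoperation cohort
#' rather than the whole population at risk: cause prevalences are
#' scaled to the mix observed among reviewed reoperations (within 2,347
#' reviewed contacts, hardware removal 870, wound treatment 624,
#' re-osteosynthesis 195, other 135, infection 114, secondary
#' arthroplasty 94, nonunion 94), with the same coding-error model as
#' [registry_config()]. This is the cohort on which algorithm
#' construction is exercised, since step selection needs enough
#' positives per cause.
#'
#' @inheritParams registry_config
#' @param ... passed to [registry_config()].
#' @export
validation_cohort_config <- function(n_fractures = 2347, seed = 1L, ...) {
  reviewed <- c(hardware_removal = 870, wound_treatment = 624,
                re_osteosynthesis = 195, other = 135, infection = 114,
                secondary_arthroplasty = 94, nonunion = 94)
  registry_config(
    n_fractures = n_fractures,
    cause_prevalences = reviewed / 2347,
    seed = seed, ...
  )
}

validate_registry_config <- function(config) {
  if (config$n_fractures < 1) {
    stop("n_fractures must be at least 1", call. = FALSE)
  }
  probs <- c(config$region_mix, config$cause_prevalences,
             config$laterality_missing_rate, config$noise_rates,
             config$decoy_overlap, config$p_second_reop, config$censoring_rate)
  if (any(probs < 0) || any(c(config$laterality_missing_rate, config$noise_rates,
                              config$decoy_overlap, config$p_second_reop,
                              config$censoring_rate, config$cause_prevalences) > 1)) {
    stop("All probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sum(config$cause_prevalences) > 1) {
    stop("Cause prevalences must sum to at most 1", call. = FALSE)
  }
  stopifnot(setequal(names(config$region_mix), region_letters()))
  for (cause in names(config$coding_model)) {
    m <- config$coding_model[[cause]]
    if (m$p_both > min(m$p_proc, m$p_diag) + 1e-12) {
      stop("coding_model for ", cause,
           ": p_both cannot exceed min(p_proc, p_diag)", call. = FALSE)
    }
  }
  config
}

# Reoperation-day windows by cause, in days since index surgery.
cause_day_window <- function(cause) {
  switch(cause,
    re_osteosynthesis = c(1, 42),
    secondary_arthroplasty = c(43, 365),
    hardware_removal = c(42, 365),
    c(1, 365)
  )
}

two_digits <- function(n) sprintf("%02d", sample(11:98, n, replace = TRUE))

draw_decoy_proc <- function(region, overlap) {
  n <- length(region)
  hit <- stats::runif(n) < overlap
  ifelse(hit,
         paste0("KN", region, "J", two_digits(n)),
         paste0("KN", region, "B9", sample(0:9, n, replace = TRUE)))
}

correct_proc_code <- function(cause, region) {
  n <- length(region)
  switch(cause,
    infection = paste0("KN", region, sample(c("W69", "W59"), n, replace = TRUE)),
    nonunion = paste0("KN", region, "T5", sample(0:9, n, replace = TRUE)),
    re_osteosynthesis = paste0("KN", region, "J", two_digits(n)),
    secondary_arthroplasty = paste0("KN", region, "C", two_digits(n)),
    hardware_removal = paste0("KN", region, "U2", sample(0:9, n, replace = TRUE)),
    wound_treatment = paste0("KQ", region, "E", two_digits(n)),
    other = NULL
  )
}

correct_diag_code <- function(cause, n) {
  switch(cause,
    infection = rep("DT846", n),
    nonunion = sample(c("DT813O", "DM841"), n, replace = TRUE),
    re_osteosynthesis = paste0("DT84", sample(0:4, n, replace = TRUE)),
    NULL
  )
}

#' Generate a synthetic registry cohort
#'
#' Draws, per fracture: region and side, an index osteosynthesis
#' procedure, a true reoperation cause (or none) at the configured
#' prevalences, a reoperation day uniform within the cause's admissible
#' window (within 42 days for early re-osteosynthesis, after day 42 for
#' secondary arthroplasty, from day 42 for hardware removal, anywhere in
#' the follow-up year otherwise), and contact codes through the
#' coding-error model; then injects noise contacts (emergency-room
#' visits, new fractures, chronic-wound care, planned wire/fixator
#' removal, contralateral surgery) at the configured rates. Fixed seed
#' gives bit-identical cohorts.
#'
#' @param config a [registry_config()].
#' @param seed overrides `config$seed` when given.
#' @return a `reop_cohort`: list with tibbles `index`, `events`, `gold`,
#'   the per-fracture generation log `draws`, and the `config`.
#' @export
simulate_registry <- function(config = registry_config(), seed = NULL) {
  validate_registry_config(config)
  seed <- seed %||% config$seed
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  n <- config$n_fractures
  regions <- sample(names(config$region_mix), n, replace = TRUE,
                    prob = config$region_mix)
  sides <- sample(c("left", "right"), n, replace = TRUE)
  index <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    fracture_id = sprintf("F%06d", seq_len(n)),
    surgery_date = config$start_date + sample(0:364, n, replace = TRUE),
    procedure = paste0("KN", regions, "J", two_digits(n)),
    region = regions,
    laterality = sides
  )

  prev <- config$cause_prevalences
  true_cause <- sample(c(names(prev), "not_reoperation"), n, replace = TRUE,
                       prob = c(prev, 1 - sum(prev)))

  draws <- tibble::tibble(
    fracture_id = index$fracture_id, region = regions, side = sides,
    true_cause = true_cause, reop_day = NA_integer_,
    proc_correct = NA, diag_correct = NA, censored_at = NA_integer_
  )

  contacts <- list()  # each: fracture_id, day, side, procs, diags, source

  # --- true reoperation contacts ---------------------------------------
  for (cause in names(prev)) {
    idx <- which(true_cause == cause)
    if (length(idx) == 0) next
    m <- length(idx)
    w <- cause_day_window(cause)
    day <- sample(w[1]:w[2], m, replace = TRUE)
    cm <- config$coding_model[[cause]] %||% list(p_proc = 0, p_diag = 0, p_both = 0)
    # joint correctness classes: both / procedure only / diagnosis only /
    # neither, with P(both) binding
    u <- stats::runif(m)
    cls <- dplyr::case_when(
      u < cm$p_both ~ "both",
      u < cm$p_proc ~ "proc",
      u < cm$p_proc + (cm$p_diag - cm$p_both) ~ "diag",
      .default = "neither"
    )
    proc_ok <- cls %in% c("both", "proc")
    diag_ok <- cls %in% c("both", "diag")
    reg <- regions[idx]
    procs <- draw_decoy_proc(reg, config$decoy_overlap)
    if (!is.null(correct_proc_code(cause, reg[1]))) {
      procs[proc_ok] <- correct_proc_code(cause, reg[proc_ok])
    }
    diags <- rep("DZ479", m)  # nonspecific aftercare diagnosis decoy
    cd <- correct_diag_code(cause, m)
    if (!is.null(cd)) diags[diag_ok] <- cd[diag_ok]
    side <- ifelse(stats::runif(m) < config$laterality_missing_rate,
                   "unspecified", sides[idx])
    contacts[[length(contacts) + 1]] <- tibble::tibble(
      fracture_idx = idx, day = day, side = side,
      proc = procs, diag = diags, source = paste0("reop_", cause)
    )
    draws$reop_day[idx] <- day
    draws$proc_correct[idx] <- proc_ok
    draws$diag_correct[idx] <- diag_ok
  }

  # --- optional second, lower-severity reoperation ---------------------
  if (config$p_second_reop > 0) {
    major <- which(true_cause %in% c("infection", "nonunion",
                                     "re_osteosynthesis", "secondary_arthroplasty"))
    second <- major[stats::runif(length(major)) < config$p_second_reop]
    if (length(second) > 0) {
      m <- length(second)
      contacts[[length(contacts) + 1]] <- tibble::tibble(
        fracture_idx = second,
        day = sample(42:365, m, replace = TRUE),
        side = sides[second],
        proc = paste0("KN", regions[second], "U2", sample(0:9, m, replace = TRUE)),
        diag = "DZ479", source = "second_reop_hardware_removal"
      )
    }
  }

  # --- noise contacts --------------------------------------------------
  noise <- function(rate) which(stats::runif(n) < rate)
  nr <- config$noise_rates
  add_noise <- function(idx, side, proc, diag, source) {
    if (length(idx) == 0) return()
    contacts[[length(contacts) + 1]] <<- tibble::tibble(
      fracture_idx = idx, day = sample(1:365, length(idx), replace = TRUE),
      side = side, proc = proc, diag = diag, source = source
    )
  }
  i <- noise(nr[["er_visit"]])
  add_noise(i, sides[i], draw_decoy_proc(regions[i], config$decoy_overlap),
            "DZ479", "noise_er_visit")
  i <- noise(nr[["new_fracture"]])
  add_noise(i, sides[i], draw_decoy_proc(regions[i], config$decoy_overlap),
            "DS429", "noise_new_fracture")
  i <- noise(nr[["chronic_wound"]])
  add_noise(i, sides[i], paste0("KQ", regions[i], "E", two_digits(length(i))),
            "DL979", "noise_chronic_wound")
  i <- noise(nr[["kwire_removal"]])
  add_noise(i, sides[i], paste0("KN", regions[i], "U19"), "DZ479",
            "noise_kwire_removal")
  i <- noise(nr[["exfix_removal"]])
  add_noise(i, sides[i], paste0("KN", regions[i], "U49"), "DZ479",
            "noise_exfix_removal")
  i <- noise(nr[["contralateral"]])
  add_noise(i, ifelse(sides[i] == "left", "right", "left"),
            draw_decoy_proc(regions[i], config$decoy_overlap), "DZ479",
            "noise_contralateral")

  contacts <- dplyr::bind_rows(contacts)

  # --- censoring: follow-up truncated before a planned reoperation -----
  if (config$censoring_rate > 0 && nrow(contacts) > 0) {
    cens_idx <- which(stats::runif(n) < config$censoring_rate)
    cens_day <- sample(1:365, length(cens_idx), replace = TRUE)
    draws$censored_at[cens_idx] <- cens_day
    cut <- rep(366L, n)
    cut[cens_idx] <- cens_day
    keep <- contacts$day <= cut[contacts$fracture_idx]
    contacts <- contacts[keep, , drop = FALSE]
    lost <- cens_idx[!is.na(draws$reop_day[cens_idx]) &
                       draws$reop_day[cens_idx] > cens_day]
    true_cause[lost] <- "not_reoperation"
    draws$true_cause <- true_cause
  }

  # --- flatten contacts into one event row per code --------------------
  if (nrow(contacts) > 0) {
    contacts <- contacts |>
      dplyr::mutate(
        fracture_id = index$fracture_id[.data$fracture_idx],
        patient_id = index$patient_id[.data$fracture_idx],
        date = index$surgery_date[.data$fracture_idx] + .data$day,
        contact_id = sprintf("C%06d", dplyr::row_number())
      )
    events <- dplyr::bind_rows(
      contacts |>
        dplyr::transmute(.data$patient_id, .data$contact_id, .data$date,
                         kind = "procedure", code = .data$proc,
                         laterality = .data$side),
      contacts |>
        dplyr::filter(!is.na(.data$diag)) |>
        dplyr::transmute(.data$patient_id, .data$contact_id, .data$date,
                         kind = "diagnosis", code = .data$diag,
                         laterality = .data$side)
    ) |>
      dplyr::arrange(.data$patient_id, .data$date, .data$contact_id, .data$kind)
  } else {
    events <- tibble::tibble(
      patient_id = character(), contact_id = character(),
      date = as.Date(character()), kind = character(), code = character(),
      laterality = character()
    )
  }

  gold <- tibble::tibble(
    fracture_id = index$fracture_id,
    true_cause = true_cause,
    source = "synthetic"
  )
  log <- contacts
  structure(
    list(index = index, events = events, gold = gold, draws = draws,
         contacts_log = if (nrow(contacts) > 0) {
           contacts |> dplyr::select("fracture_id", "contact_id", "day",
                                     "side", "proc", "diag", "source")
         } else contacts,
         config = config),
    class = "reop_cohort"
  )
}

#' @export
print.reop_cohort <- function(x, ...) {
  cat("Synthetic registry cohort: ", nrow(x$index), " index fractures, ",
      nrow(x$events), " coded events (seed ", x$config$seed, ")\n", sep = "")
  print(dplyr::count(x$gold, .data$true_cause, sort = TRUE))
  invisible(x)
}

#' Summarize a synthetic cohort
#'
#' Calibration report: per-cause counts and prevalences, observed
#' coding-correctness rates among true reoperations (to compare with
#' the configured coding model), and noise-contact counts.
#'
#' @param cohort a `reop_cohort`.
#' @return list with tibbles `causes`, `coding`, `noise`.
#' @export
summarize_cohort <- function(cohort) {
  n <- nrow(cohort$index)
  causes <- cohort$gold |>
    dplyr::count(.data$true_cause, name = "n_fractures") |>
    dplyr::mutate(prevalence = .data$n_fractures / n) |>
    dplyr::arrange(dplyr::desc(.data$n_fractures))
  coding <- cohort$draws |>
    dplyr::filter(.data$true_cause != "not_reoperation",
                  !is.na(.data$proc_correct)) |>
    dplyr::group_by(.data$true_cause) |>
    dplyr::summarise(
      n = dplyr::n(),
      p_correct_procedure = mean(.data$proc_correct),
      p_correct_diagnosis = mean(.data$diag_correct),
      p_both = mean(.data$proc_correct & .data$diag_correct),
      p_either = mean(.data$proc_correct | .data$diag_correct),
      .groups = "drop"
    )
  noise <- if (nrow(cohort$contacts_log) > 0) {
    cohort$contacts_log |>
      dplyr::filter(startsWith(.data$source, "noise_")) |>
      dplyr::count(.data$source, name = "n_contacts")
  } else {
    tibble::tibble(source = character(), n_contacts = integer())
  }
  list(causes = causes, coding = coding, noise = noise)
}

#' Write a cohort to registry-format files
#'
#' Emits the same CSV tables the readers consume (`events.csv`,
#' `index_surgeries.csv`, `gold_labels.csv`) plus a JSON generation
#' report.
#'
#' @param cohort a `reop_cohort`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    events = file.path(dir, "events.csv"),
    index = file.path(dir, "index_surgeries.csv"),
    gold = file.path(dir, "gold_labels.csv"),
    report = file.path(dir, "generation_report.json")
  )
  write_events(cohort$events, paths[["events"]])
  write_index_surgeries(cohort$index, paths[["index"]])
  write_gold_labels(cohort$gold, paths[["gold"]])
  s <- summarize_cohort(cohort)
  jsonlite::write_json(
    list(n_fractures = nrow(cohort$index), seed = cohort$config$seed,
         causes = s$causes, coding = s$coding, noise = s$noise),
    paths[["report"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
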