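#' Registry table input/output
#'
#' Readers and writers for the two longitudinal tables the pipeline
#' consumes: coded hospital-contact events (one row per code) and index
#' surgeries (one row per fracture). Registry exports differ in column
#' naming and delimiter, so both readers take a dialect that remaps
#' columns; dates are ISO-8601 at day resolution. Ingest never silently
#' drops rows: malformed rows are rejected with a line-numbered report
#' attached to the result, and accepted + rejected always equals the
#' input row count.
#'
#' @name registry-io
NULL

#' Registry file dialect
#'
#' @param delim field delimiter, default comma.
#' @param columns named character vector remapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(patient_id = "cpr_hash", date = "d_odto")`. Canonical names not
#'   listed are looked up verbatim.
#' @return dialect object (list).
#' @export
registry_dialect <- function(delim = ",", columns = character()) {
  list(delim = delim, columns = columns)
}

file_column <- function(dialect, canonical) {
  unname(dialect$columns[canonical] %|chr|% canonical)
}

`%|chr|%` <- function(x, default) {
  ifelse(is.na(x), default, x)
}

read_registry_table <- function(path, dialect, required, optional = character()) {
  raw <- readr::read_delim(
    path, delim = dialect$delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  need <- file_column(dialect, required)
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("Input file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cols <- file_column(dialect, c(required, optional))
  present <- cols %in% names(raw)
  out <- raw[, cols[present], drop = FALSE]
  names(out) <- c(required, optional)[present]
  out
}

finish_ingest <- function(data, reject_reason, path, what) {
  bad <- !is.na(reject_reason)
  rejects <- tibble::tibble(
    line = which(bad) + 1L,  # +1 for the header line
    reason = reject_reason[bad]
  )
  kept <- data[!bad, , drop = FALSE]
  if (nrow(rejects) > 0) {
    message("read ", what, " from ", path, ": ", nrow(kept), " accepted, ",
            nrow(rejects), " rejected (see attr(x, \"rejects\"))")
  }
  attr(kept, "rejects") <- rejects
  attr(kept, "n_input") <- nrow(data)
  kept
}

#' Read coded hospital-contact events
#'
#' Expects columns `patient_id`, `contact_id`, `date`, `code` and
#' optionally `kind` (derived from the code's leading letter when
#' absent) and `laterality` (`left`/`right`, anything else treated as
#' unspecified). Rows with unparseable dates or empty codes are rejected
#' with a line-numbered report in `attr(x, "rejects")`.
#'
#' @param path delimited text file with a header.
#' @param dialect a [registry_dialect()].
#' @return tibble of events: `patient_id`, `contact_id`, `date` (Date),
#'   `kind`, `code`, `laterality`.
#' @export
read_events <- function(path, dialect = registry_dialect()) {
  raw <- read_registry_table(
    path, dialect,
    required = c("patient_id", "contact_id", "date", "code"),
    optional = c("kind", "laterality")
  )
  out <- tibble::tibble(
    patient_id = raw$patient_id,
    contact_id = raw$contact_id,
    date = suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d")),
    code = normalize_code(raw$code),
    kind = if ("kind" %in% names(raw)) tolower(raw$kind) else code_kind(raw$code),
    laterality = normalize_laterality(
      if ("laterality" %in% names(raw)) raw$laterality else NA_character_
    )
  )
  out$kind[is.na(out$kind) | out$kind == ""] <- code_kind(out$code[is.na(out$kind) | out$kind == ""])
  reason <- dplyr::case_when(
    is.na(raw$patient_id) | raw$patient_id == "" ~ "empty patient_id",
    is.na(out$date) ~ "unparseable date",
    is.na(raw$code) | trimws(raw$code) == "" ~ "empty code",
    !out$kind %in% c("procedure", "diagnosis") ~ "unknown code kind",
    .default = NA_character_
  )
  finish_ingest(out[c("patient_id", "contact_id", "date", "kind", "code", "laterality")],
                reason, path, "events")
}

normalize_laterality <- function(x) {
  x <- tolower(trimws(as.character(x)))
  dplyr::case_when(
    x %in% c("left", "l", "sin", "sinister") ~ "left",
    x %in% c("right", "r", "dxt", "dexter") ~ "right",
    .default = "unspecified"
  )
}

#' Read index surgeries
#'
#' One row per fracture (a patient with several fractures contributes
#' one row each). Expects `patient_id`, `fracture_id`, `surgery_date`,
#' `procedure` and optionally `region` and `laterality`; when a region
#' column is present it must agree with the region letter of the
#' procedure code, otherwise the row is rejected as inconsistent. When
#' absent, the region is derived from the code.
#'
#' @inheritParams read_events
#' @return tibble: `patient_id`, `fracture_id`, `surgery_date` (Date),
#'   `procedure`, `region`, `laterality`.
#' @export
read_index_surgeries <- function(path, dialect = registry_dialect()) {
  raw <- read_registry_table(
    path, dialect,
    required = c("patient_id", "fracture_id", "surgery_date", "procedure"),
    optional = c("region", "laterality")
  )
  derived <- code_region(raw$procedure)
  out <- tibble::tibble(
    patient_id = raw$patient_id,
    fracture_id = raw$fracture_id,
    surgery_date = suppressWarnings(as.Date(raw$surgery_date, format = "%Y-%m-%d")),
    procedure = normalize_code(raw$procedure),
    region = if ("region" %in% names(raw)) toupper(trimws(raw$region)) else derived,
    laterality = normalize_laterality(
      if ("laterality" %in% names(raw)) raw$laterality else NA_character_
    )
  )
  reason <- dplyr::case_when(
    is.na(raw$patient_id) | raw$patient_id == "" ~ "empty patient_id",
    is.na(raw$fracture_id) | raw$fracture_id == "" ~ "empty fracture_id",
    is.na(out$surgery_date) ~ "unparseable date",
    is.na(raw$procedure) | trimws(raw$procedure) == "" ~ "empty procedure code",
    !startsWith(out$procedure, "KN") ~ "index procedure outside chapter KN",
    !is.na(derived) & out$region != derived ~ "region inconsistent with procedure code",
    .default = NA_character_
  )
  if (anyDuplicated(out$fracture_id[is.na(reason)])) {
    dup <- duplicated(out$fracture_id) & is.na(reason)
    reason[dup] <- "duplicate fracture_id"
  }
  finish_ingest(out, reason, path, "index surgeries")
}

#' Read fracture-level gold labels
#'
#' @inheritParams read_events
#' @return tibble: `fracture_id`, `true_cause`, `source`
#'   (`"synthetic"` or `"chart_review"`).
#' @export
read_gold_labels <- function(path, dialect = registry_dialect()) {
  raw <- read_registry_table(
    path, dialect,
    required = c("fracture_id", "true_cause"), optional = "source"
  )
  out <- tibble::tibble(
    fracture_id = raw$fracture_id,
    true_cause = raw$true_cause,
    source = if ("source" %in% names(raw)) raw$source else "chart_review"
  )
  reason <- dplyr::case_when(
    is.na(out$fracture_id) | out$fracture_id == "" ~ "empty fracture_id",
    !out$true_cause %in% cause_levels() ~ "unknown cause label",
    duplicated(out$fracture_id) ~ "duplicate fracture_id",
    .default = NA_character_
  )
  finish_ingest(out, reason, path, "gold labels")
}

#' Write registry tables
#'
#' Plain CSV writers (dates as ISO-8601) matching the corresponding
#' readers, so `read_events(write_events(x))` is the identity.
#'
#' @param x tibble to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
write_index_surgeries <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
write_gold_labels <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
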