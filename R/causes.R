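#' Reoperation cause labels and severity
#'
#' When one fracture has several reoperations within follow-up, the
#' fracture is labelled with the most severe cause. Severity, in
#' descending order: infection, nonunion, re-osteosynthesis, secondary
#' arthroplasty, hardware removal, wound treatment, other. A fracture
#' with no qualifying reoperation is `not_reoperation`, below all.
#'
#' @name causes
NULL

CAUSE_LEVELS <- c(
  "infection", "nonunion", "re_osteosynthesis", "secondary_arthroplasty",
  "hardware_removal", "wound_treatment", "other", "not_reoperation"
)

#' Cause labels in descending severity order
#' @return character vector of the eight labels, most severe first.
#' @export
cause_levels <- function() CAUSE_LEVELS

#' Severity rank of a cause
#'
#' @param cause character vector of cause labels.
#' @return integer rank, 1 = most severe (infection), 8 = not_reoperation.
#' @export
severity_rank <- function(cause) {
  r <- match(as.character(cause), CAUSE_LEVELS)
  if (anyNA(r) && !anyNA(cause)) {
    stop("Unknown cause label(s): ",
         paste(setdiff(unique(cause), CAUSE_LEVELS), collapse = ", "),
         call. = FALSE)
  }
  r
}

#' Most severe cause among several
#'
#' Deterministic roll-up used at fracture level: among all labels for one
#' fracture's reoperations, keep the most severe. Invariant to input
#' order.
#'
#' @param causes non-empty character vector of cause labels.
#' @return single cause label.
#' @examples
#' worst_cause(c("hardware_removal", "infection"))  # "infection"
#' @export
worst_cause <- function(causes) {
  causes <- causes[!is.na(causes)]
  if (length(causes) == 0) stop("worst_cause() needs at least one label", call. = FALSE)
  CAUSE_LEVELS[min(severity_rank(causes))]
}

#' Major/minor composite of a cause
#'
#' Major reoperations: infection, nonunion, early re-osteosynthesis and
#' secondary arthroplasty. Minor: hardware removal and wound treatment.
#'
#' @param cause character vector of cause labels.
#' @return character vector with values `"major"`, `"minor"`, `"other"`,
#'   `"none"`.
#' @export
composite_label <- function(cause) {
  dplyr::case_match(
    as.character(cause),
    c("infection", "nonunion", "re_osteosynthesis", "secondary_arthroplasty") ~ "major",
    c("hardware_removal", "wound_treatment") ~ "minor",
    "other" ~ "other",
    "not_reoperation" ~ "none"
  )
}
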