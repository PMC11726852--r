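#' NOMESCO / ICD-10 code semantics
#'
#' Danish hospital registries code surgical procedures with NOMESCO codes
#' (chapter prefix "K", e.g. `KNGJ21`: chapter `KN` = musculoskeletal,
#' region letter `G` = knee/lower leg, then the procedure stem) and
#' diagnoses with the Danish ICD-10 dialect (leading "D", no dot, e.g.
#' `DT846`). These helpers implement pattern matching over such codes:
#' prefix templates with an anatomical-region wildcard (`KNxU` matches
#' `KNGU29` for any region letter), contiguous code ranges
#' (`DT840`--`DT844`), region extraction, and laterality compatibility.
#'
#' @name code-system
NULL

# The seven anatomical region letters used by musculoskeletal chapters:
# B shoulder/upper arm, C elbow/forearm, D wrist/hand, E pelvis,
# F hip/thigh, G knee/lower leg, H ankle/foot.
REGION_LETTERS <- c("B", "C", "D", "E", "F", "G", "H")

#' Anatomical region letters
#'
#' @return Character vector of the seven region letters `B`..`H` used at
#'   position 3 of musculoskeletal NOMESCO codes.
#' @export
region_letters <- function() REGION_LETTERS

#' Normalize clinical codes
#'
#' Uppercases and trims codes so that registry extracts with mixed case
#' compare correctly against templates.
#'
#' @param x character vector of codes.
#' @return character vector, uppercase, whitespace-trimmed.
#' @export
normalize_code <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Kind of a clinical code
#'
#' @param x character vector of codes.
#' @return `"procedure"` for codes starting with "K", `"diagnosis"` for
#'   codes starting with "D", `NA` otherwise.
#' @export
code_kind <- function(x) {
  x <- normalize_code(x)
  ifelse(startsWith(x, "K"), "procedure",
         ifelse(startsWith(x, "D"), "diagnosis", NA_character_))
}

#' Construct a code-pattern table
#'
#' A pattern is a prefix template, optionally with the wildcard `x` (or
#' `X`) at the anatomical-region position (position 3 of a K-chapter
#' template, e.g. `KNxW69`), or a contiguous range given by `range_end`
#' (e.g. `DT840`--`DT844`). Patterns are stored as tibbles so code sets
#' compose with ordinary `dplyr::bind_rows()`.
#'
#' @param template character vector of templates.
#' @param kind `"procedure"` or `"diagnosis"`; defaults to the kind
#'   implied by the first letter of each template.
#' @param range_end optional end of a contiguous range (same length as
#'   `template` or length 1); `NA` for plain prefix patterns.
#' @return tibble with columns `template`, `range_end`, `kind`.
#' @export
code_pattern <- function(template, kind = NULL, range_end = NA_character_) {
  template <- normalize_pattern(template)
  if (is.null(kind)) kind <- code_kind(sub("X", "A", template, fixed = TRUE))
  tibble::tibble(
    template = template,
    range_end = normalize_code(range_end) %|NA|% NA_character_,
    kind = kind
  )
}

`%|NA|%` <- function(x, default) {
  x[is.na(x) | x == "NA" | x == ""] <- default
  x
}

# Uppercase a template but keep the wildcard canonical as "X"; validate
# wildcard placement (only position 3 of a K-chapter template).
normalize_pattern <- function(template) {
  template <- normalize_code(template)
  bad <- vapply(template, function(t) {
    pos <- which(strsplit(t, "")[[1]] == "X")
    length(pos) > 1 || (length(pos) == 1 && !(pos == 3 && startsWith(t, "K")))
  }, logical(1))
  if (any(bad)) {
    stop(
      "Malformed code template(s): ", paste(template[bad], collapse = ", "),
      " (wildcard allowed only at the region position of a K-chapter template)",
      call. = FALSE
    )
  }
  template
}

#' Match codes against a single pattern
#'
#' Prefix semantics: a template matches any code that extends it, with
#' the wildcard standing for any of the seven region letters. A range
#' pattern matches codes whose prefix of the template's length falls
#' lexicographically within `[template, range_end]`.
#'
#' @param codes character vector of codes to test.
#' @param template a single template string.
#' @param range_end optional single range end.
#' @return logical vector along `codes`.
#' @examples
#' code_matches(c("KNGW69", "KNGW59"), "KNxW69")
#' code_matches("DT842", "DT840", range_end = "DT844")
#' @export
code_matches <- function(codes, template, range_end = NULL) {
  stopifnot(length(template) == 1)
  codes <- normalize_code(codes)
  template <- normalize_pattern(template)
  if (!is.null(range_end) && !is.na(range_end) && nzchar(range_end)) {
    range_end <- normalize_code(range_end)
    if (nchar(range_end) != nchar(template) || substr(range_end, 1, nchar(template) - 1) != substr(template, 1, nchar(template) - 1)) {
      stop("Range ends must differ from the template only in the final part: ",
           template, "-", range_end, call. = FALSE)
    }
    if (template > range_end) {
      stop("Range start exceeds range end: ", template, "-", range_end, call. = FALSE)
    }
    pre <- substr(codes, 1, nchar(template))
    return(!is.na(pre) & nchar(codes) >= nchar(template) & pre >= template & pre <= range_end)
  }
  tl <- nchar(template)
  long_enough <- !is.na(codes) & nchar(codes) >= tl
  pre <- substr(codes, 1, tl)
  if (substr(template, 3, 3) == "X") {
    long_enough &
      substr(pre, 1, 2) == substr(template, 1, 2) &
      substr(pre, 3, 3) %in% REGION_LETTERS &
      substr(pre, 4, tl) == substr(template, 4, tl)
  } else {
    long_enough & pre == template
  }
}

#' Match codes against a pattern table
#'
#' @param codes character vector of codes.
#' @param patterns tibble as produced by [code_pattern()].
#' @return `TRUE` if any code matches any pattern of its own kind.
#' @export
matches_any <- function(codes, patterns) {
  any(code_hits(codes, patterns))
}

# Per-code hit vector against a whole pattern table (kind-aware).
code_hits <- function(codes, patterns) {
  hit <- logical(length(codes))
  if (length(codes) == 0 || nrow(patterns) == 0) return(hit)
  kinds <- code_kind(codes)
  for (i in seq_len(nrow(patterns))) {
    sel <- !is.na(kinds) & kinds == patterns$kind[i] & !hit
    if (any(sel)) {
      hit[sel] <- code_matches(codes[sel], patterns$template[i],
                               patterns$range_end[i])
    }
  }
  hit
}

# Row-wise any-match over a list-column of code vectors, vectorized by
# flattening once instead of looping rows.
match_rows <- function(codes_list, patterns) {
  out <- logical(length(codes_list))
  if (length(codes_list) == 0 || nrow(patterns) == 0) return(out)
  idx <- rep(seq_along(codes_list), lengths(codes_list))
  codes <- unlist(codes_list, use.names = FALSE)
  hit <- code_hits(codes, patterns)
  out[unique(idx[hit])] <- TRUE
  out
}

#' Anatomical region of a procedure code
#'
#' Musculoskeletal (`KN`) codes carry the region letter at position 3.
#' Other surgical chapters (skin `KQ`, nervous system `KA`) do not
#' always follow this convention; how they map is configurable. The
#' default reads the position-3 letter when it is one of `B`..`H` and
#' otherwise treats the code as region-neutral (`NA`), which passes the
#' same-anatomical-area filter for any index region.
#'
#' @param codes character vector of codes.
#' @param chapter_regions how non-`KN` K-chapters map to regions:
#'   `"positional"` (default, read position 3) or a named list mapping a
#'   2-letter chapter to a fixed region letter or `NA`.
#' @return character vector of region letters, `NA` where region-neutral
#'   or not a procedure code.
#' @examples
#' code_region("KNGJ21")  # "G"
#' code_region("DT846")   # NA: diagnosis codes carry no region
#' @export
code_region <- function(codes, chapter_regions = "positional") {
  codes <- normalize_code(codes)
  out <- rep(NA_character_, length(codes))
  proc <- !is.na(codes) & startsWith(codes, "K") & nchar(codes) >= 3
  if (identical(chapter_regions, "positional")) {
    letter <- substr(codes, 3, 3)
    ok <- proc & letter %in% REGION_LETTERS
    out[ok] <- letter[ok]
  } else {
    chap <- substr(codes, 1, 2)
    kn <- proc & chap == "KN"
    letter <- substr(codes, 3, 3)
    ok <- kn & letter %in% REGION_LETTERS
    out[ok] <- letter[ok]
    for (ch in names(chapter_regions)) {
      sel <- proc & chap == ch
      val <- chapter_regions[[ch]]
      if (identical(val, "positional")) {
        ok <- sel & letter %in% REGION_LETTERS
        out[ok] <- letter[ok]
      } else {
        out[sel] <- if (is.null(val)) NA_character_ else as.character(val)
      }
    }
  }
  out
}

#' Laterality compatibility
#'
#' Two sides are compatible unless both are specified and differ:
#' missing laterality coding is common in discharge data, so an
#' unspecified side never blocks a match. The relation is symmetric.
#'
#' @param a,b character vectors with values `"left"`, `"right"`,
#'   `"unspecified"` (recycled to a common length).
#' @return logical vector.
#' @export
laterality_compatible <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  specified <- c("left", "right")
  !(a %in% specified & b %in% specified & a != b)
}

#' Laterality levels
#' @return `c("left", "right", "unspecified")`.
#' @export
laterality_levels <- function() c("left", "right", "unspecified")
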