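#' Code-set configuration
#'
#' All code sets live in one configuration object: per-cause stepwise
#' algorithms (ordered "or"-composed pattern groups plus the deployed
#' step), cause-specific day windows relative to the index surgery, and
#' the exclusion sets (planned K-wire / external-fixation removal,
#' chronic-wound care). The shipped default contains the code families
#' with established identities for each cause; the full deployed lists
#' are site-specific and user-editable, so the whole object round-trips
#' through YAML or JSON without code changes.
#'
#' Day windows: re-osteosynthesis is early revision fixation within the
#' first 6 weeks (days 1--42); secondary arthroplasty is prosthetic
#' conversion after 6 weeks (day 43 on); hardware removal counts from 6
#' weeks (day 42 on). `Inf` means "no constraint beyond the follow-up
#' window".
#'
#' @return `default_code_config()` returns the configuration list.
#' @export
default_code_config <- function() {
  list(
    chapter_regions = "positional",
    causes = list(
      infection = list(
        window = c(1, Inf),
        steps = list(
          list(name = "infection_procedure",
               patterns = code_pattern(c("KNxW69", "KNxW59"))),
          list(name = "infection_diagnosis",
               patterns = code_pattern("DT846"))
        ),
        selected_step = 2
      ),
      nonunion = list(
        window = c(1, Inf),
        steps = list(
          list(name = "nonunion_procedure",
               patterns = code_pattern("KNxT5")),
          list(name = "nonunion_diagnosis",
               patterns = code_pattern(c("DT813O", "DM841")))
        ),
        selected_step = 2
      ),
      re_osteosynthesis = list(
        window = c(1, 42),
        steps = list(
          list(name = "revision_fixation_procedure",
               patterns = code_pattern(c("KNxJ", "KNxC"))),
          list(name = "mechanical_complication_diagnosis",
               patterns = code_pattern("DT840", range_end = "DT844"))
        ),
        selected_step = 2
      ),
      secondary_arthroplasty = list(
        window = c(43, Inf),
        steps = list(
          list(name = "arthroplasty_procedure",
               patterns = code_pattern("KNxC"))
        ),
        selected_step = 1
      ),
      hardware_removal = list(
        window = c(42, Inf),
        steps = list(
          list(name = "implant_removal_procedure",
               patterns = code_pattern("KNxU"))
        ),
        selected_step = 1
      ),
      wound_treatment = list(
        window = c(1, Inf),
        steps = list(
          list(name = "skin_chapter_procedure",
               patterns = code_pattern("KQ", kind = "procedure"))
        ),
        selected_step = 1
      )
    ),
    # Exclusion sets are deployment placeholders: NOMESCO has no single
    # national convention separating planned wire/fixator removal from
    # therapeutic implant removal, so sites must adapt these stems.
    # `procedure_only` excludes a contact only when every qualifying
    # surgical code on it matches (so a contact that also performed real
    # revision surgery survives); `diagnosis_any` excludes on any
    # matching diagnosis code.
    exclusions = list(
      kwire_removal = list(
        type = "procedure_only",
        patterns = code_pattern("KNxU19")
      ),
      exfix_removal = list(
        type = "procedure_only",
        patterns = code_pattern("KNxU49")
      ),
      chronic_wound = list(
        type = "diagnosis_any",
        patterns = code_pattern(c("DL97", "DL89", "DI83"))
      )
    )
  )
}

#' Deployed patterns for a cause
#'
#' Steps compose cumulatively with "or": the patterns of step `k` are
#' the union of pattern groups 1..k. The deployed rule for a cause uses
#' its `selected_step`.
#'
#' @param config a code-set configuration.
#' @param cause a cause label with an algorithm in `config`.
#' @param step step number; defaults to the cause's `selected_step`.
#' @return pattern tibble (union over the first `step` groups).
#' @export
cause_patterns <- function(config, cause, step = NULL) {
  alg <- config$causes[[cause]]
  if (is.null(alg)) {
    stop("No algorithm configured for cause '", cause, "'", call. = FALSE)
  }
  step <- step %||% alg$selected_step
  stopifnot(step >= 1, step <= length(alg$steps))
  dplyr::bind_rows(lapply(alg$steps[seq_len(step)], `[[`, "patterns"))
}

#' Validate a code-set configuration
#'
#' Checks that every cause has at least one step, that `selected_step`
#' indexes an existing step, that windows are ordered day intervals and
#' that all pattern templates are well formed.
#'
#' @param config configuration list.
#' @return the configuration, invisibly; errors on violation.
#' @export
validate_code_config <- function(config) {
  stopifnot(is.list(config), is.list(config$causes))
  for (cause in names(config$causes)) {
    alg <- config$causes[[cause]]
    if (length(alg$steps) < 1) {
      stop("Cause '", cause, "' has no steps", call. = FALSE)
    }
    if (is.null(alg$selected_step) || alg$selected_step < 1 ||
        alg$selected_step > length(alg$steps)) {
      stop("Cause '", cause, "': selected_step must index an existing step",
           call. = FALSE)
    }
    w <- alg$window %||% c(1, Inf)
    if (length(w) != 2 || w[1] > w[2] || w[1] < 1) {
      stop("Cause '", cause, "': window must be an ordered day interval >= 1",
           call. = FALSE)
    }
    for (s in alg$steps) normalize_pattern(s$patterns$template)
  }
  for (ex in names(config$exclusions %||% list())) {
    t <- config$exclusions[[ex]]$type
    if (!t %in% c("procedure_only", "diagnosis_any", "procedure_any")) {
      stop("Exclusion '", ex, "': unknown type '", t, "'", call. = FALSE)
    }
    normalize_pattern(config$exclusions[[ex]]$patterns$template)
  }
  invisible(config)
}

pattern_to_list <- function(p) {
  lapply(seq_len(nrow(p)), function(i) {
    out <- list(template = p$template[i], kind = p$kind[i])
    if (!is.na(p$range_end[i])) out$range_end <- p$range_end[i]
    out
  })
}

pattern_from_list <- function(x) {
  dplyr::bind_rows(lapply(x, function(e) {
    code_pattern(e$template, kind = e$kind,
                 range_end = e$range_end %||% NA_character_)
  }))
}

#' Read / write a code-set configuration
#'
#' Format is chosen by extension: `.yaml`/`.yml` or `.json`.
#'
#' @param path file path.
#' @return `read_code_config()` returns a validated configuration list.
#' @export
read_code_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  config <- list(
    chapter_regions = raw$chapter_regions %||% "positional",
    causes = lapply(raw$causes, function(alg) {
      list(
        window = vapply(alg$window %||% list(1, Inf), function(v) {
          if (identical(v, ".inf") || identical(v, "Inf")) Inf else as.numeric(v)
        }, numeric(1)),
        steps = lapply(alg$steps, function(s) {
          list(name = s$name, patterns = pattern_from_list(s$patterns))
        }),
        selected_step = as.integer(alg$selected_step)
      )
    }),
    exclusions = lapply(raw$exclusions %||% list(), function(ex) {
      list(type = ex$type, patterns = pattern_from_list(ex$patterns))
    })
  )
  validate_code_config(config)
}

#' @rdname read_code_config
#' @param config configuration list to serialize.
#' @export
write_code_config <- function(config, path) {
  validate_code_config(config)
  ser <- list(
    chapter_regions = config$chapter_regions,
    causes = lapply(config$causes, function(alg) {
      list(
        window = lapply(unname(alg$window), function(v) if (is.finite(v)) v else "Inf"),
        steps = lapply(alg$steps, function(s) {
          list(name = s$name, patterns = pattern_to_list(s$patterns))
        }),
        selected_step = alg$selected_step
      )
    }),
    exclusions = lapply(config$exclusions %||% list(), function(ex) {
      list(type = ex$type, patterns = pattern_to_list(ex$patterns))
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(ser, path)
  }
  invisible(path)
}
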