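# In-code fixtures shared across test files.

make_index <- function(fracture_id = "F1", region = "G", side = "right",
                       date = as.Date("2016-03-01")) {
  tibble::tibble(
    patient_id = paste0("P", fracture_id), fracture_id = fracture_id,
    surgery_date = date, procedure = paste0("KN", region, "J21"),
    region = region, laterality = side
  )
}

# One contact = one procedure code (+ optional diagnosis codes), `day`
# days after the index surgery of `index`.
make_contact <- function(index, day, proc, diag = character(),
                         side = "unspecified", contact_id = NULL,
                         row = 1) {
  contact_id <- contact_id %||% paste0(index$fracture_id[row], "-d", day, "-", proc[1])
  tibble::tibble(
    patient_id = index$patient_id[row],
    contact_id = contact_id,
    date = index$surgery_date[row] + day,
    kind = c(rep("procedure", length(proc)), rep("diagnosis", length(diag))),
    code = c(proc, diag),
    laterality = side
  )
}

`%||%` <- rlang::`%||%`

# Independent 2x2 helpers used as oracles (deliberately written from the
# defining formulas, not via the package's own functions).
oracle_kappa <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
  (po - pe) / (1 - pe)
}
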