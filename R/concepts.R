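#' Coded concept
#'
#' A minimal terminology binding: a code from a named code system plus a
#' human-readable display. ICD-10 is used for diagnoses, LOINC for clinical
#' parameters, and local `urn:dmp:*` systems for platform-internal codes.
#'
#' @param system code-system identifier (non-empty string)
#' @param code code within the system (non-empty string)
#' @param display human-readable label
#' @return an object of class `coded_concept`
#' @export
coded_concept <- function(system, code, display = code) {
  stopifnot(is.character(system), nzchar(system),
            is.character(code), nzchar(code))
  structure(list(system = system, code = code, display = display),
            class = "coded_concept")
}

#' @export
print.coded_concept <- function(x, ...) {
  cat(sprintf("<%s> %s (%s)\n", x$system, x$code, x$display))
  invisible(x)
}

SYS_ICD10 <- "http://hl7.org/fhir/sid/icd-10"
SYS_LOINC <- "http://loinc.org"
SYS_DMP <- "urn:dmp:code"

#' ICD-10 concept shorthand
#' @param code ICD-10 code such as "I10" or "E11.9"
#' @param display optional label
#' @export
icd10 <- function(code, display = code) {
  if (!grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", code))
    stop("not a valid ICD-10 code: ", code)
  coded_concept(SYS_ICD10, code, display)
}

#' Clinical parameter catalogue
#'
#' The fixed vocabulary of quantitative parameters the platform reads from
#' the record, prefills on pathway pages, and sets goals against. Parameters
#' are addressed throughout by their short `key`; LOINC codes are carried for
#' interoperability.
#'
#' @return data.frame with columns key, system, code, display, unit
#' @export
param_catalog <- function() {
  data.frame(
    key = c("sbp", "dbp", "fpg", "hba1c", "ldl", "hdl", "tg", "tchol",
            "bmi", "weight", "height", "waist", "egfr", "score10y"),
    system = c(rep(SYS_LOINC, 13L), SYS_DMP),
    code = c("8480-6", "8462-4", "1558-6", "4548-4", "13457-7", "2085-9",
             "2571-8", "2093-3", "39156-5", "29463-7", "8302-2", "8280-0",
             "33914-3", "score10y"),
    display = c("Systolic blood pressure", "Diastolic blood pressure",
                "Fasting plasma glucose", "Hemoglobin A1c",
                "LDL cholesterol", "HDL cholesterol", "Triglyceride",
                "Total cholesterol", "Body mass index", "Body weight",
                "Body height", "Waist circumference",
                "Estimated glomerular filtration rate",
                "10-year cardiovascular risk score"),
    unit = c("mmHg", "mmHg", "mg/dL", "%", "mmol/L", "mmol/L", "mmol/L",
             "mmol/L", "kg/m2", "kg", "cm", "cm", "mL/min/1.73m2", "%"),
    stringsAsFactors = FALSE
  )
}

#' Look up a parameter by key
#' @param key short parameter key (see [param_catalog()])
#' @return a `coded_concept`; the catalogue unit is available via the
#'   catalogue itself
#' @export
param_concept <- function(key) {
  cat_ <- param_catalog()
  i <- match(key, cat_$key)
  if (is.na(i)) stop("unknown parameter key: ", key)
  coded_concept(cat_$system[i], cat_$code[i], cat_$display[i])
}

param_unit <- function(key) {
  cat_ <- param_catalog()
  i <- match(key, cat_$key)
  if (is.na(i)) stop("unknown parameter key: ", key)
  cat_$unit[i]
}

# map a (system, code) pair back to a catalogue key, or NA
param_key_for <- function(system, code) {
  cat_ <- param_catalog()
  i <- which(cat_$system == system & cat_$code == code)
  if (length(i)) cat_$key[i[1L]] else NA_character_
}

#' Glucose and cholesterol unit conversion
#'
#' Conventional and SI units coexist in primary-care records: glucose rules
#' are stated in mg/dL while lipid targets use mmol/L. Molar masses give the
#' conversion factors 18.018 (glucose) and 38.67 (cholesterol).
#'
#' @param x value(s) to convert
#' @param to target unit, `"mg/dL"` or `"mmol/L"`
#' @return converted numeric
#' @export
convert_glucose <- function(x, to = c("mmol/L", "mg/dL")) {
  to <- match.arg(to)
  if (to == "mmol/L") x / 18.018 else x * 18.018
}

#' @rdname convert_glucose
#' @export
convert_cholesterol <- function(x, to = c("mmol/L", "mg/dL")) {
  to <- match.arg(to)
  if (to == "mmol/L") x / 38.67 else x * 38.67
}
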