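# Declarative eligibility/transition predicates.
#
# A predicate is a finite expression tree of atoms combined with all/any/not.
# Atoms close over the patient-state vocabulary the platform rules use: age,
# active coded conditions, ongoing medication classes, validity-aware
# observation comparisons, prior encounters, and the computed risk category.
# The same trees drive module eligibility and page-flow transitions, and they
# serialise naturally to YAML/JSON.

PRED_ATOMS <- c("age_cmp", "has_condition", "on_medication_class",
                "observation_cmp", "has_prior_encounter", "risk_category_is",
                "always", "never")
PRED_OPS <- c(">", ">=", "<", "<=", "==")

#' Predicate atoms and combinators
#'
#' Constructors for the declarative predicate language used by module
#' eligibility rules and page-flow transitions.
#'
#' * `p_age(op, years)` — completed age compared to a bound.
#' * `p_condition(codes)` — any active condition whose ICD-10 code starts
#'   with one of `codes` (so `"E11"` matches `"E11.9"`); code ranges like
#'   `"E10-E14"` are expanded.
#' * `p_medication(tag)` — an ongoing medication carrying a therapeutic class
#'   tag.
#' * `p_observation(code, op, value, validity_months)` — the latest *fresh*
#'   observation of a parameter satisfies a comparison; expired or absent
#'   observations make the atom false. In-session entered values take
#'   precedence over the stored record.
#' * `p_prior_encounter(module, type, within_months)` — a completed encounter
#'   of the module/track within a window.
#' * `p_risk(levels)` — the current risk category is one of `levels`.
#' * `p_always()`, `p_never()` — constants.
#' * `p_all(...)`, `p_any(...)`, `p_not(x)` — combinators.
#'
#' @param op comparison operator, one of `">"`, `">="`, `"<"`, `"<="`, `"=="`
#' @param years,value numeric bound
#' @param codes character vector of ICD-10 prefixes or `"A00-A09"` ranges
#' @param tag therapeutic class tag
#' @param code parameter key (see [param_catalog()])
#' @param validity_months freshness window for the observation
#' @param module,type,within_months prior-encounter constraint
#' @param levels risk category level(s)
#' @param ... sub-predicates
#' @param x sub-predicate
#' @name predicates
NULL

#' @rdname predicates
#' @export
p_age <- function(op, years) {
  op <- match.arg(op, PRED_OPS)
  structure(list(atom = "age_cmp", op = op, years = as.numeric(years)),
            class = "dmp_predicate")
}

#' @rdname predicates
#' @export
p_condition <- function(codes) {
  structure(list(atom = "has_condition", codes = expand_icd10_range(codes)),
            class = "dmp_predicate")
}

#' @rdname predicates
#' @export
p_medication <- function(tag) {
  structure(list(atom = "on_medication_class", tag = as.character(tag)),
            class = "dmp_predicate")
}

#' @rdname predicates
#' @export
p_observation <- function(code, op, value, validity_months = NULL) {
  op <- match.arg(op, PRED_OPS)
  atom <- list(atom = "observation_cmp", code = code, op = op,
               value = as.numeric(value))
  if (!is.null(validity_months)) atom$validity_months <- as.numeric(validity_months)
  structure(atom, class = "dmp_predicate")
}

#' @rdname predicates
#' @export
p_prior_encounter <- function(module, type, within_months = NULL) {
  atom <- list(atom = "has_prior_encounter", module = module, type = type)
  if (!is.null(within_months)) atom$within_months <- as.numeric(within_months)
  structure(atom, class = "dmp_predicate")
}

#' @rdname predicates
#' @export
p_risk <- function(levels) {
  structure(list(atom = "risk_category_is", levels = as.character(levels)),
            class = "dmp_predicate")
}

#' @rdname predicates
#' @export
p_always <- function() structure(list(atom = "always"), class = "dmp_predicate")

#' @rdname predicates
#' @export
p_never <- function() structure(list(atom = "never"), class = "dmp_predicate")

#' @rdname predicates
#' @export
p_all <- function(...) structure(list(all = lapply(list(...), as_predicate)),
                                 class = "dmp_predicate")

#' @rdname predicates
#' @export
p_any <- function(...) structure(list(any = lapply(list(...), as_predicate)),
                                 class = "dmp_predicate")

#' @rdname predicates
#' @export
p_not <- function(x) structure(list(not = as_predicate(x)), class = "dmp_predicate")

as_predicate <- function(x) {
  if (inherits(x, "dmp_predicate")) return(x)
  if (!is.list(x)) stop("not a predicate: ", deparse(x))
  structure(x, class = "dmp_predicate")
}

# "E10-E14" -> c("E10","E11","E12","E13","E14"); plain prefixes pass through
expand_icd10_range <- function(codes) {
  out <- character()
  for (cd in codes) {
    m <- regmatches(cd, regexec("^([A-Z])([0-9]{2})-([A-Z])([0-9]{2})$", cd))[[1L]]
    if (length(m)) {
      if (m[2] != m[4]) stop("ICD-10 range must stay within one letter block: ", cd)
      out <- c(out, sprintf("%s%02d", m[2], as.integer(m[3]):as.integer(m[5])))
    } else out <- c(out, cd)
  }
  unique(out)
}

#' Evaluation context for predicates
#'
#' Bundles everything a predicate can look at: the patient dataset, the
#' reference date, the current risk category (if computed) and any values
#' entered during an active encounter session (which shadow the stored
#' record for `observation_cmp` atoms).
#'
#' @param dataset a `patient_dataset`
#' @param as_of reference date
#' @param risk_category current risk category or `NA`
#' @param session_values named list key -> numeric of in-session entries
#' @export
predicate_context <- function(dataset, as_of, risk_category = NA_character_,
                              session_values = list()) {
  list(dataset = dataset, as_of = as.Date(as_of),
       risk_category = risk_category, session_values = session_values)
}

cmp <- function(a, op, b) switch(op,
  ">" = a > b, ">=" = a >= b, "<" = a < b, "<=" = a <= b, "==" = a == b)

#' Evaluate a predicate
#' @param pred a `dmp_predicate`
#' @param ctx a [predicate_context()]
#' @return logical scalar
#' @export
eval_predicate <- function(pred, ctx) {
  pred <- as_predicate(pred)
  if (!is.null(pred$all))
    return(all(vapply(pred$all, eval_predicate, TRUE, ctx = ctx)))
  if (!is.null(pred$any))
    return(length(pred$any) > 0L && any(vapply(pred$any, eval_predicate, TRUE, ctx = ctx)))
  if (!is.null(pred$not)) return(!eval_predicate(pred$not, ctx))
  switch(pred$atom,
    always = TRUE,
    never = FALSE,
    age_cmp = cmp(age_at(ctx$dataset$patient$birth_date, ctx$as_of), pred$op, pred$years),
    has_condition = has_active_condition(ctx$dataset, pred$codes, ctx$as_of),
    on_medication_class = on_medication_class(ctx$dataset, pred$tag, ctx$as_of),
    observation_cmp = {
      v <- ctx$session_values[[pred$code]]
      if (is.null(v)) {
        hit <- latest_observation(ctx$dataset, pred$code, ctx$as_of, pred$validity_months)
        if (is.null(hit$observation) || hit$freshness == "expired") return(FALSE)
        v <- hit$observation$value
      }
      cmp(v, pred$op, pred$value)
    },
    has_prior_encounter = {
      lower <- if (is.null(pred$within_months)) as.Date("0001-01-01")
               else add_months(ctx$as_of, -pred$within_months)
      any(vapply(ctx$dataset$encounters, function(e)
        e$module_id == pred$module && e$encounter_type == pred$type &&
          e$date <= ctx$as_of && e$date >= lower, TRUE))
    },
    risk_category_is = !is.na(ctx$risk_category) && ctx$risk_category %in% pred$levels,
    stop("unknown predicate atom: ", pred$atom)
  )
}

#' Human-readable one-line rendering of a predicate
#' @param pred a `dmp_predicate`
#' @return character scalar
#' @export
describe_predicate <- function(pred) {
  pred <- as_predicate(pred)
  if (!is.null(pred$all))
    return(paste0("(", paste(vapply(pred$all, describe_predicate, ""), collapse = " AND "), ")"))
  if (!is.null(pred$any))
    return(paste0("(", paste(vapply(pred$any, describe_predicate, ""), collapse = " OR "), ")"))
  if (!is.null(pred$not)) return(paste0("NOT ", describe_predicate(pred$not)))
  switch(pred$atom,
    always = "always",
    never = "never",
    age_cmp = sprintf("age %s %g", pred$op, pred$years),
    has_condition = sprintf("active condition in {%s}", paste(pred$codes, collapse = ",")),
    on_medication_class = sprintf("on %s medication", pred$tag),
    observation_cmp = sprintf("%s %s %g%s", pred$code, pred$op, pred$value,
                              if (is.null(pred$validity_months)) ""
                              else sprintf(" (fresh within %g mo)", pred$validity_months)),
    has_prior_encounter = sprintf("prior %s %s%s", pred$module, pred$type,
                                  if (is.null(pred$within_months)) ""
                                  else sprintf(" within %g mo", pred$within_months)),
    risk_category_is = sprintf("risk category in {%s}", paste(pred$levels, collapse = ",")))
}

# every leaf atom must use a known atom name, known parameter keys, and a
# known comparison operator; returns character vector of problems
validate_predicate <- function(pred, where = "predicate") {
  pred <- tryCatch(as_predicate(pred), error = function(e) NULL)
  if (is.null(pred)) return(paste0(where, ": not a predicate"))
  probs <- character()
  if (!is.null(pred$all) || !is.null(pred$any)) {
    kids <- pred$all %||% pred$any
    for (i in seq_along(kids))
      probs <- c(probs, validate_predicate(kids[[i]], sprintf("%s[%d]", where, i)))
    return(probs)
  }
  if (!is.null(pred$not)) return(validate_predicate(pred$not, paste0(where, "/not")))
  if (is.null(pred$atom) || !pred$atom %in% PRED_ATOMS)
    return(paste0(where, ": unknown atom '", pred$atom %||% "<missing>", "'"))
  if (pred$atom %in% c("age_cmp", "observation_cmp") && !pred$op %in% PRED_OPS)
    probs <- c(probs, paste0(where, ": bad operator"))
  if (pred$atom == "observation_cmp" &&
      !pred$code %in% param_catalog()$key)
    probs <- c(probs, paste0(where, ": unknown parameter key '", pred$code, "'"))
  if (pred$atom == "has_condition" && length(pred$codes) == 0L)
    probs <- c(probs, paste0(where, ": empty condition code set"))
  probs
}

# plain-list form (for YAML round trips); class tags are dropped
predicate_to_list <- function(pred) {
  pred <- as_predicate(pred)
  out <- unclass(pred)
  if (!is.null(out$all)) out$all <- lapply(out$all, predicate_to_list)
  if (!is.null(out$any)) out$any <- lapply(out$any, predicate_to_list)
  if (!is.null(out$not)) out$not <- predicate_to_list(out$not)
  out
}

predicate_from_list <- function(x) {
  if (!is.list(x)) stop("predicate config must be a mapping")
  if (!is.null(x$all)) return(structure(list(all = lapply(x$all, predicate_from_list)), class = "dmp_predicate"))
  if (!is.null(x$any)) return(structure(list(any = lapply(x$any, predicate_from_list)), class = "dmp_predicate"))
  if (!is.null(x$not)) return(structure(list(not = predicate_from_list(x$not)), class = "dmp_predicate"))
  x$codes <- if (!is.null(x$codes)) unlist(x$codes)
  x$levels <- if (!is.null(x$levels)) unlist(x$levels)
  structure(x[!vapply(x, is.null, TRUE)], class = "dmp_predicate")
}
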