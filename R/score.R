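# SCORE-family 10-year fatal cardiovascular risk.
#
# The platform's cardiovascular module references a nationally calibrated
# member of the SCORE family. The published SCORE methodology models
# cause-specific (coronary and non-coronary cardiovascular) fatal-event
# survival with Weibull baselines in age and proportional hazards in the
# risk factors; the 10-year risk is the sum of the two cause-specific
# conditional event probabilities between the current age and age + 10.
# Coefficient tables are data: the table shipped here is a demonstration
# calibration using the published low-risk-region SCORE coefficients and
# must not be taken for any national calibration.

#' SCORE risk coefficient table
#'
#' @param survival data.frame(sex, endpoint, alpha, p): per-sex Weibull
#'   baseline parameters for the coronary (`"chd"`) and non-coronary
#'   (`"non_chd"`) strata
#' @param loghr data.frame(endpoint, smoker, sbp, tchol): log hazard ratios
#'   for current smoking, systolic blood pressure (per mmHg above 120) and
#'   total cholesterol (per mmol/L above 6)
#' @param calibration free-text label of where the numbers come from
#' @export
risk_coefficient_table <- function(survival, loghr, calibration) {
  stopifnot(all(c("sex", "endpoint", "alpha", "p") %in% names(survival)),
            all(c("endpoint", "smoker", "sbp", "tchol") %in% names(loghr)),
            all(is.finite(survival$alpha)), all(is.finite(survival$p)),
            all(survival$p > 0))
  structure(list(survival = survival, loghr = loghr, calibration = calibration),
            class = "risk_coefficient_table")
}

#' Demonstration SCORE coefficient table
#'
#' The published low-risk-region SCORE coefficients, shipped as a clearly
#' labelled demonstration calibration (see [risk_coefficient_table()]).
#' @export
score_demo_coefficients <- function() {
  risk_coefficient_table(
    survival = data.frame(
      sex = c("male", "male", "female", "female"),
      endpoint = c("chd", "non_chd", "chd", "non_chd"),
      alpha = c(-22.1, -26.7, -29.8, -31.0),
      p = c(4.71, 5.64, 6.36, 6.62),
      stringsAsFactors = FALSE),
    loghr = data.frame(
      endpoint = c("chd", "non_chd"),
      smoker = c(0.71, 0.63),
      sbp = c(0.018, 0.022),
      tchol = c(0.24, 0.02),
      stringsAsFactors = FALSE),
    calibration = "demonstration: published SCORE low-risk-region coefficients (not a national calibration)")
}

#' Default risk-category cut points
#'
#' Conventional SCORE banding of the 10-year fatal risk:
#' below 1 percent low, 1 to below 5 moderate, 5 to below 10 high,
#' 10 percent and above very high.
#' @return named numeric vector of lower bounds (percent)
#' @export
default_risk_thresholds <- function() c(moderate = 1, high = 5, very_high = 10)

#' 10-year fatal cardiovascular risk (SCORE functional form)
#'
#' Computes the Weibull-survival SCORE risk: for each endpoint stratum the
#' baseline survivals to the current age and to age + 10 are
#' `S0(a) = exp(-exp(alpha) * (a - 20)^p)`, raised to
#' `exp(w)` with `w` the linear predictor in smoking, systolic pressure
#' (centred at 120 mmHg) and total cholesterol (centred at 6 mmol/L); the
#' stratum's 10-year event probability is `1 - S(age+10)/S(age)` and the
#' total risk is the sum over the coronary and non-coronary strata, capped
#' at 100 percent. Deterministic; categorised by `thresholds`.
#'
#' @param age age in years, 30 to 90
#' @param sex `"female"` or `"male"`
#' @param smoker logical, current smoker
#' @param sbp systolic blood pressure in mmHg, 70 to 260
#' @param total_cholesterol total cholesterol in mmol/L, 2 to 12
#' @param table a [risk_coefficient_table()]
#' @param thresholds named lower bounds in percent, see
#'   [default_risk_thresholds()]
#' @return object of class `risk_result`: `ten_year_risk_percent`,
#'   `category`, `inputs_used`
#' @export
cvd_risk_score <- function(age, sex, smoker, sbp, total_cholesterol,
                           table = score_demo_coefficients(),
                           thresholds = default_risk_thresholds()) {
  sex <- match.arg(sex, c("female", "male"))
  if (age < 30 || age > 90) stop("age out of range [30, 90]: ", age)
  if (sbp < 70 || sbp > 260) stop("sbp out of range [70, 260] mmHg: ", sbp)
  if (total_cholesterol < 2 || total_cholesterol > 12)
    stop("total cholesterol out of range [2, 12] mmol/L: ", total_cholesterol)
  smoker <- isTRUE(smoker)
  total <- 0
  for (ep in c("chd", "non_chd")) {
    surv <- table$survival[table$survival$sex == sex & table$survival$endpoint == ep, ]
    hr <- table$loghr[table$loghr$endpoint == ep, ]
    s_now <- exp(-exp(surv$alpha) * (age - 20)^surv$p)
    s_10 <- exp(-exp(surv$alpha) * (age + 10 - 20)^surv$p)
    w <- hr$tchol * (total_cholesterol - 6) + hr$sbp * (sbp - 120) + hr$smoker * smoker
    total <- total + (1 - (s_10^exp(w)) / (s_now^exp(w)))
  }
  pct <- min(100, 100 * total)
  th <- sort(thresholds)
  category <- "low"
  for (nm in names(th)) if (pct >= th[[nm]]) category <- nm
  structure(list(ten_year_risk_percent = pct, category = category,
                 inputs_used = list(age = age, sex = sex, smoker = smoker,
                                    sbp = sbp, total_cholesterol = total_cholesterol,
                                    calibration = table$calibration)),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("10-year fatal cardiovascular risk: %.2f%% (%s)\n",
              x$ten_year_risk_percent, x$category))
  cat("  calibration:", x$inputs_used$calibration, "\n")
  invisible(x)
}

#' Wrap a risk result in a decision-support card
#' @param risk a `risk_result`
#' @return a `cds_card` of kind `risk_score`
#' @export
risk_score_card <- function(risk) {
  cds_card("cvd_risk_score", "risk_score",
           payload = list(concept = param_concept("score10y"),
                          value = risk$ten_year_risk_percent, unit = "%",
                          category = risk$category),
           rationale = sprintf("10-year fatal cardiovascular risk %.2f%% (%s category)",
                               risk$ten_year_risk_percent, risk$category))
}
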