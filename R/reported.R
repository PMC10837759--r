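#' Reported national aggregate counts
#'
#' Loads the cumulative operational counts published for the Turkish
#' national Disease Management Platform (as of 18 September 2023), shipped
#' with the package as plain CSV: per-module encounter counts, target
#' population coverage counts, the January 2023 monthly targets, and overall
#' aggregates. These are the raw *counts*; every rate is recomputed from
#' them by the population-tracking functions, which is how the published
#' percentages are reproduced.
#'
#' @param which one of `"encounters"`, `"coverage"`, `"achievement"`,
#'   `"overall"`
#' @return data.frame
#' @export
reported_counts <- function(which = c("encounters", "coverage", "achievement", "overall")) {
  which <- match.arg(which)
  file <- switch(which,
    encounters = "reported_encounters_by_module.csv",
    coverage = "reported_coverage_counts.csv",
    achievement = "reported_monthly_achievement.csv",
    overall = "reported_overall_counts.csv")
  path <- system.file("extdata", file, package = "dmpkit", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
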