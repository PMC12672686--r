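#' Cohort demographics summarizer
#'
#' Summarizes a per-state demographic count table (counts of patients per
#' variable/category/disease state) into overall and per-state percentages.
#'
#' @name demographics
NULL

#' Load the bundled disease-cohort demographic counts
#'
#' Per-state patient counts by gender, race and ethnicity for the 68-patient
#' MGUS/SMM/NDMM/RRMM cohort the package's presets are patterned on.
#'
#' @return data.frame with columns `variable`, `category`, `MGUS`, `SMM`,
#'   `NDMM`, `RRMM`.
#' @export
cohort_demographics <- function() {
  path <- system.file("extdata", "cohort_demographics.csv",
                      package = "raredrop", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Summarize demographic counts into percentages
#'
#' @param counts data.frame as from [cohort_demographics()]: one row per
#'   (variable, category), one count column per disease state.
#' @return data.frame adding `n` (overall count) and `percent` (overall
#'   percentage within each variable, rounded to 2 decimals).
#' @export
summarize_demographics <- function(counts) {
  state_cols <- setdiff(names(counts), c("variable", "category"))
  n <- rowSums(counts[, state_cols, drop = FALSE])
  out <- counts
  out$n <- n
  totals <- stats::ave(n, counts$variable, FUN = sum)
  out$percent <- round(100 * n / totals, 2)
  out
}

#' Overall percentage for one demographic category
#'
#' @param counts count table (see [summarize_demographics()]).
#' @param variable,category row selector, e.g. `("Gender", "Male")`.
#' @return percentage (0-100, rounded to 2 decimals).
#' @export
demographic_percent <- function(counts, variable, category) {
  s <- summarize_demographics(counts)
  row <- s[s$variable == variable & s$category == category, ]
  if (nrow(row) != 1) stop("no unique row for ", variable, "/", category)
  row$percent
}
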