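#' Apply respondent-level exclusions
#'
#' Drops respondents who are pregnant, outside the coded 18-64 age range, or
#' underweight (BMI < 18.5 kg/m^2), in that priority order: a record
#' matching several criteria is tallied once, under the first matching
#' reason. A record *missing* a criterion field is never excluded by that
#' criterion — missing data are resolved later by imputation, and dropping
#' here would confound the two stages. Age is operationalised through the
#' five coded categories (1 = 18-24 ... 5 = 55-64); any age category outside
#' 1..5 is treated as over-65 and excluded.
#'
#' @param records respondent microdata data.frame.
#' @return list with `records` (retained rows) and `tally`, a named integer
#'   vector with counts `pregnant`, `age_over_65`, `underweight_bmi`,
#'   `retained`; the four always sum to the input row count.
#' @export
apply_exclusions <- function(records) {
  stopifnot_microdata(records, c("pregnant", "age_category", "bmi"))
  pregnant <- !is.na(records$pregnant) & records$pregnant == 1
  age_out <- !is.na(records$age_category) &
    !(records$age_category %in% 1:5)
  underweight <- !is.na(records$bmi) & records$bmi < 18.5

  reason <- rep(NA_character_, nrow(records))
  reason[underweight] <- "underweight_bmi"
  reason[age_out] <- "age_over_65"       # earlier reasons overwrite later ones
  reason[pregnant] <- "pregnant"

  keep <- is.na(reason)
  tally <- c(pregnant = sum(reason == "pregnant", na.rm = TRUE),
             age_over_65 = sum(reason == "age_over_65", na.rm = TRUE),
             underweight_bmi = sum(reason == "underweight_bmi", na.rm = TRUE),
             retained = sum(keep))
  hwd_log("INFO", "cohort",
          "exclusions: %d pregnant, %d over-65, %d underweight; %d retained",
          tally[["pregnant"]], tally[["age_over_65"]],
          tally[["underweight_bmi"]], tally[["retained"]])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, tally = tally)
}

#' Assess per-state analysability
#'
#' A state is ineligible when (a) any analysis variable exceeds the
#' missingness threshold (default: more than 50% missing), or (b) the
#' observed income-category (8 levels) by race/ethnicity (6 levels)
#' cross-tabulation contains an empty cell whose row and column marginals
#' are both non-zero. Both checks run on observed, pre-imputation data.
#' Ineligible states are dropped from all downstream stages.
#'
#' @param records respondent microdata (post-exclusion).
#' @param missing_threshold fraction in (0, 1]; a variable strictly above it
#'   flags the state.
#' @param states state labels to assess; defaults to those present in the
#'   data. A listed state with zero records is ineligible for both reasons
#'   (with a warning).
#' @return data.frame with columns `state`, `eligible`, `reasons`
#'   (comma-separated subset of `excess_missingness`, `zero_crosstab_cell`;
#'   empty string iff eligible).
#' @export
assess_state_eligibility <- function(records, missing_threshold = 0.5,
                                     states = sort(unique(records$state))) {
  stopifnot_microdata(records)
  if (!is.numeric(missing_threshold) || missing_threshold <= 0 ||
      missing_threshold > 1) {
    stop("`missing_threshold` must lie in (0, 1]", call. = FALSE)
  }
  analysis_vars <- setdiff(MICRODATA_COLUMNS, c("state", "pregnant"))
  rows <- lapply(states, function(s) {
    sub <- records[records$state == s, , drop = FALSE]
    reasons <- character()
    if (nrow(sub) == 0) {
      warning(sprintf("state %s has zero records", s), call. = FALSE)
      reasons <- c("excess_missingness", "zero_crosstab_cell")
    } else {
      miss <- vapply(analysis_vars, function(v) mean(is.na(sub[[v]])), 0)
      if (any(miss > missing_threshold)) reasons <- "excess_missingness"
      tab <- table(factor(sub$income_category, levels = 1:8),
                   factor(sub$race_ethnicity, levels = 1:6))
      zero_active <- tab == 0 &
        outer(rowSums(tab) > 0, colSums(tab) > 0)
      if (any(zero_active)) reasons <- c(reasons, "zero_crosstab_cell")
    }
    if (length(reasons)) {
      hwd_log("INFO", "cohort", "state %s ineligible: %s", s,
              paste(reasons, collapse = ", "))
    }
    data.frame(state = s, eligible = length(reasons) == 0,
               reasons = paste(reasons, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
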