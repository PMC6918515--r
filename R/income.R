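# Income dollar assignment, poverty-guideline ratios, and the two
# low/middle/high classification schemes.

# Top-of-range dollar values for the 8 ordinal BRFSS income categories.
# The open-ended top category is assigned its floor, $75,000 — the most
# optimistic (conservative-for-disparity) assignment.
.INCOME_CATEGORY_DOLLARS <- c(9999, 14999, 19999, 24999, 34999, 49999, 74999, 75000)

#' Assign a dollar income to an ordinal income category
#'
#' Each of the eight ordinal household-income categories is mapped to the
#' highest dollar value possible in its range (e.g. the `<$10,000` category
#' becomes $9,999); the open-ended `>= $75,000` category is assigned
#' $75,000.
#'
#' @param income_category integer vector with values in 1..8 (NA allowed).
#' @return numeric vector of assigned dollar incomes (NA where input NA).
#' @export
assign_income_dollars <- function(income_category) {
  bad <- !is.na(income_category) & !(income_category %in% 1:8)
  if (any(bad)) {
    stop("income_category out of range 1..8: ",
         paste(unique(income_category[bad]), collapse = ", "), call. = FALSE)
  }
  .INCOME_CATEGORY_DOLLARS[income_category]
}

#' Read a poverty-guideline table
#'
#' The table gives, per guideline region (`contiguous_and_DC`, `alaska`,
#' `hawaii`), the dollar guideline for a one-person household
#' (`base_dollars`) and the increment per additional household member
#' (`increment_dollars`). The packaged file
#' `poverty_guidelines_2016.csv` holds the HHS guidelines effective
#' January 2016.
#'
#' @param path file path; default is the packaged 2016 table.
#' @return data.frame with columns `region`, `year`, `base_dollars`,
#'   `increment_dollars`, of class `hwd_guideline_table`.
#' @export
load_poverty_guidelines <- function(path = system.file("extdata",
                                                       "poverty_guidelines_2016.csv",
                                                       package = "hwdisparity")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("region", "year", "base_dollars", "increment_dollars")
  if (!all(required %in% names(tab))) {
    stop("guideline table must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$base_dollars <= 0) || any(tab$increment_dollars <= 0)) {
    stop("guideline base and increment dollars must be positive", call. = FALSE)
  }
  class(tab) <- c("hwd_guideline_table", "data.frame")
  tab
}

# Guideline region for a state label; Alaska and Hawaii have their own HHS
# rows, everything else (incl. DC) uses the contiguous table.
guideline_region <- function(state) {
  ifelse(state %in% c("Alaska", "AK"), "alaska",
         ifelse(state %in% c("Hawaii", "HI"), "hawaii", "contiguous_and_DC"))
}

#' Income-to-poverty-guideline ratio (percent of poverty level)
#'
#' Computes `100 * income / guideline(household size)` where the guideline
#' is `base + (size - 1) * increment` for the region matching the state.
#'
#' @param assigned_income dollar incomes (from [assign_income_dollars()]).
#' @param household_size total household members (adults + children), >= 1.
#' @param state state labels, used only to pick the guideline region.
#' @param guidelines a guideline table from [load_poverty_guidelines()].
#' @return numeric vector of percent-of-poverty-level ratios (NA where any
#'   input is NA).
#' @export
poverty_ratio <- function(assigned_income, household_size, state, guidelines) {
  if (any(!is.na(household_size) & household_size < 1)) {
    stop("household_size must be >= 1", call. = FALSE)
  }
  region <- guideline_region(state)
  idx <- match(region, guidelines$region)
  if (anyNA(idx)) {
    stop("guideline table lacks region(s): ",
         paste(unique(region[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  guideline <- guidelines$base_dollars[idx] +
    (household_size - 1) * guidelines$increment_dollars[idx]
  100 * assigned_income / guideline
}

#' 75th percentile with linear interpolation (Hazen definition)
#'
#' Percentile definition used for the state-specific high-income cut point:
#' plotting position `h = n*p + 1/2` with linear interpolation between
#' order statistics (type 5 in the Hyndman-Fan taxonomy). On
#' `{100, 200, 300, 400}` the 75th percentile is 350. A survey-weighted
#' variant interpolates the weighted cumulative distribution at the same
#' plotting positions.
#'
#' @param x numeric values (NA dropped).
#' @param p probability, default 0.75.
#' @param weights optional positive weights for a weighted percentile.
#' @return the percentile value.
#' @export
percentile_hazen <- function(x, p = 0.75, weights = NULL) {
  keep <- !is.na(x)
  x <- x[keep]
  n <- length(x)
  if (n == 0) stop("no non-missing values", call. = FALSE)
  if (is.null(weights)) {
    ord <- order(x)
    xs <- x[ord]
    h <- n * p + 0.5
    if (h <= 1) return(xs[1])
    if (h >= n) return(xs[n])
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  } else {
    w <- weights[keep]
    if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
    ord <- order(x)
    xs <- x[ord]; ws <- w[ord]
    # Hazen plotting positions on the weighted ECDF: midpoints of the
    # cumulative weight steps, rescaled to [0, 1].
    cw <- cumsum(ws) - ws / 2
    pos <- cw / sum(ws)
    if (p <= pos[1]) return(xs[1])
    if (p >= pos[length(pos)]) return(xs[length(xs)])
    stats::approx(pos, xs, xout = p, ties = "ordered")$y
  }
}

#' Classify respondents under the state-specific (RHWDI) scheme
#'
#' Within one state: `low` iff the percent-of-poverty ratio is at or below
#' 185; `middle` iff above 185 but at or below the state-specific 75th
#' percentile of the ratio distribution; `high` iff above that percentile.
#' The percentile is computed on the same classified population
#' (non-missing ratios), unweighted by default.
#'
#' @param ratios percent-of-poverty ratios for one state's respondents.
#' @param weights optional survey weights; used for the percentile only
#'   when `weighted = TRUE`.
#' @param weighted logical; survey-weighted 75th percentile (default
#'   `FALSE`, the deterministic unweighted definition).
#' @return list with `group` (character vector: `low`/`middle`/`high`, NA
#'   where the ratio is missing) and `p75` (the state cut point).
#' @export
classify_rhwdi_groups <- function(ratios, weights = NULL, weighted = FALSE) {
  if (all(is.na(ratios))) {
    stop("at least one non-missing poverty ratio is required", call. = FALSE)
  }
  p75 <- percentile_hazen(ratios, 0.75,
                          weights = if (weighted) weights else NULL)
  if (p75 <= 185) {
    warning(sprintf("degenerate state: p75 (%.1f) <= 185; middle group empty",
                    p75), call. = FALSE)
  }
  group <- ifelse(ratios <= 185, "low",
                  ifelse(ratios <= p75, "middle", "high"))
  list(group = group, p75 = p75)
}

#' Classify income categories under the fixed-dollar (HWDI) scheme
#'
#' Low: annual household income below $35,000 (categories 1-5); middle:
#' $35,000 to below $75,000 (categories 6-7); high: $75,000 or more
#' (category 8).
#'
#' @param income_category integer vector in 1..8 (NA allowed).
#' @return character vector `low`/`middle`/`high` (NA preserved).
#' @export
hwdi_income_group <- function(income_category) {
  bad <- !is.na(income_category) & !(income_category %in% 1:8)
  if (any(bad)) {
    stop("income_category out of range 1..8: ",
         paste(unique(income_category[bad]), collapse = ", "), call. = FALSE)
  }
  c("low", "low", "low", "low", "low", "middle", "middle",
    "high")[as.integer(income_category)]
}

#' Append both scheme labels to one state's completed dataset
#'
#' Convenience wrapper over [assign_income_dollars()], [poverty_ratio()],
#' [classify_rhwdi_groups()] and [hwdi_income_group()]: adds columns
#' `assigned_income`, `poverty_ratio`, `rhwdi_group`, `hwdi_group` to a
#' single state's (post-imputation, complete) microdata; the state's 75th
#' percentile cut point is attached as attribute `"p75"`.
#'
#' @param state_data one state's complete microdata.
#' @param guidelines poverty-guideline table.
#' @param weighted_p75 use the survey-weighted percentile.
#' @return `state_data` with the four classification columns appended.
#' @export
classify_income_groups <- function(state_data, guidelines, weighted_p75 = FALSE) {
  inc <- assign_income_dollars(state_data$income_category)
  size <- state_data$n_adults + state_data$n_children
  ratio <- poverty_ratio(inc, pmax(size, 1), state_data$state, guidelines)
  cls <- classify_rhwdi_groups(ratio, weights = state_data$survey_weight,
                               weighted = weighted_p75)
  state_data$assigned_income <- inc
  state_data$poverty_ratio <- ratio
  state_data$rhwdi_group <- cls$group
  state_data$hwdi_group <- hwdi_income_group(state_data$income_category)
  attr(state_data, "p75") <- cls$p75
  state_data
}
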