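# The two disparity indices and the magnitude ranking of states.

#' Healthy Weight Disparity Index (national 24.9 reference)
#'
#' `HWDI = (24.9 - high) + (mid - 24.9) + (low - 24.9)`, algebraically
#' `low + mid - high - 24.9`, where the inputs are the income-group mean
#' BMIs. 24.9 kg/m^2 is the top of the healthy-weight band.
#'
#' @param low_bmi,mid_bmi,high_bmi income-group mean BMIs (kg/m^2).
#' @return index value (kg/m^2 scale); `NA` if any input is missing.
#' @export
hwdi <- function(low_bmi, mid_bmi, high_bmi) {
  (24.9 - high_bmi) + (mid_bmi - 24.9) + (low_bmi - 24.9)
}

#' Revised Healthy Weight Disparity Index (state-mean reference)
#'
#' `RHWDI = (mean - high) + (mid - mean) + (low - mean)`, algebraically
#' `low + mid - high - mean`, with the state's own adjusted mean BMI as
#' reference. Negative values indicate greater mean BMI among high-income
#' groups than among middle- and low-income groups.
#'
#' @param state_mean_bmi state-average adjusted BMI (kg/m^2).
#' @param low_bmi,mid_bmi,high_bmi income-group mean BMIs (kg/m^2).
#' @return index value; `NA` if any input is missing.
#' @export
rhwdi <- function(state_mean_bmi, low_bmi, mid_bmi, high_bmi) {
  (state_mean_bmi - high_bmi) + (mid_bmi - state_mean_bmi) +
    (low_bmi - state_mean_bmi)
}

#' Rank states by disparity magnitude
#'
#' States are ranked by ascending absolute index value — rank 1 is the
#' smallest disparity magnitude, with the sign carried separately as a
#' negativity flag. Ties in magnitude are broken by the unrounded signed
#' value, then alphabetically by state label. Non-computable states (NA
#' index) are omitted from the ranking and reported.
#'
#' @param values numeric index values.
#' @param states state labels, same length.
#' @return data.frame with `state`, `value`, `negative`, `rank` for
#'   computable states (rank a bijection onto 1..n); attribute
#'   `non_computable` lists omitted states.
#' @export
rank_states <- function(values, states) {
  if (length(values) != length(states)) {
    stop("`values` and `states` must have equal length", call. = FALSE)
  }
  ok <- !is.na(values)
  if (!any(ok)) {
    out <- data.frame(state = character(), value = numeric(),
                      negative = logical(), rank = integer())
    attr(out, "non_computable") <- states
    hwd_log("WARN", "indices", "all states non-computable; empty ranking")
    return(out)
  }
  v <- values[ok]; s <- states[ok]
  ord <- order(abs(v), v, s)
  out <- data.frame(state = s[ord], value = v[ord], negative = v[ord] < 0,
                    rank = seq_along(ord))
  attr(out, "non_computable") <- states[!ok]
  out
}

#' Disparity index table for a set of states
#'
#' Combines pooled adjusted means (from [state_group_means()], stacked over
#' states) into one record per state: HWDI from the fixed-dollar scheme's
#' group means against the 24.9 reference, RHWDI from the poverty-ratio
#' scheme's group means against the state's overall adjusted mean, plus
#' magnitude ranks under each index.
#'
#' @param means_table row-bound [state_group_means()] output for >= 1
#'   states.
#' @return data.frame with columns `state`, `hwdi`, `rhwdi`,
#'   `rhwdi_negative`, `hwdi_rank`, `rhwdi_rank`, `computable`.
#' @export
disparity_index_table <- function(means_table) {
  pick <- function(st, sc, g) {
    r <- means_table$state == st & means_table$scheme == sc &
      means_table$group == g
    if (!any(r)) return(NA_real_)
    means_table$adjusted_mean[r][1]
  }
  states <- unique(means_table$state)
  rec <- do.call(rbind, lapply(states, function(st) {
    data.frame(
      state = st,
      hwdi = hwdi(pick(st, "hwdi", "low"), pick(st, "hwdi", "middle"),
                  pick(st, "hwdi", "high")),
      rhwdi = rhwdi(pick(st, "rhwdi", "overall"), pick(st, "rhwdi", "low"),
                    pick(st, "rhwdi", "middle"), pick(st, "rhwdi", "high"))
    )
  }))
  rk_r <- rank_states(rec$rhwdi, rec$state)
  rk_h <- rank_states(rec$hwdi, rec$state)
  rec$rhwdi_negative <- !is.na(rec$rhwdi) & rec$rhwdi < 0
  rec$rhwdi_rank <- rk_r$rank[match(rec$state, rk_r$state)]
  rec$hwdi_rank <- rk_h$rank[match(rec$state, rk_h$state)]
  rec$computable <- !is.na(rec$rhwdi) & !is.na(rec$hwdi)
  rownames(rec) <- NULL
  rec
}
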