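# Survey-weighted, covariate-adjusted mean BMI per state: fit a weighted
# linear model of BMI on demographics + income group, then recover group
# means by marginal standardisation (g-computation) and pool over the m
# imputed datasets.

#' Fit the state BMI adjustment model
#'
#' Weighted least squares of BMI on indicator-coded age category,
#' race/ethnicity, sex, education, and the three-level income group of the
#' requested scheme, with the survey weights as case weights. Reference
#' levels are the first category of each factor. Single-level factors are
#' dropped; aliased columns in a rank-deficient design are dropped with a
#' warning.
#'
#' @param data one completed (no missing values) state dataset carrying an
#'   income-group column for the scheme.
#' @param scheme `"rhwdi"` or `"hwdi"`; selects the `rhwdi_group` or
#'   `hwdi_group` column.
#' @return an `lm` fit.
#' @export
fit_bmi_model <- function(data, scheme = c("rhwdi", "hwdi")) {
  scheme <- match.arg(scheme)
  group_col <- paste0(scheme, "_group")
  stopifnot_microdata(data, c("bmi", "age_category", "race_ethnicity", "sex",
                              "education", "survey_weight", group_col))
  df <- data.frame(
    bmi = data$bmi,
    age_category = factor(data$age_category),
    race_ethnicity = factor(data$race_ethnicity),
    sex = factor(data$sex),
    education = factor(data$education),
    income_group = factor(data[[group_col]], levels = c("low", "middle", "high")),
    .w = data$survey_weight
  )
  df$income_group <- droplevels(df$income_group)
  terms <- c("age_category", "race_ethnicity", "sex", "education", "income_group")
  terms <- terms[vapply(terms, function(v) nlevels(df[[v]]) > 1, TRUE)]
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fit <- stats::lm(stats::as.formula(paste("bmi ~", rhs)), data = df,
                   weights = .w)
  if (anyNA(stats::coef(fit))) {
    warning("rank-deficient BMI model design; aliased columns dropped",
            call. = FALSE)
  }
  fit
}

#' Marginal (g-computation) adjusted mean BMI
#'
#' For a target income group `g`: sets every respondent's income group to
#' `g`, predicts BMI from the fitted model, and returns the survey-weighted
#' mean of the predictions — i.e. the group mean standardised to the
#' state's observed covariate distribution. For `target = "overall"`,
#' predictions are taken at the observed income groups, which under
#' weighted least squares with an intercept equals the weighted raw mean of
#' BMI.
#'
#' @param fit model from [fit_bmi_model()] (fitted on `data`).
#' @param data the dataset the model was fitted on.
#' @param weights survey weights (defaults to `data$survey_weight`).
#' @param target `"overall"`, `"low"`, `"middle"` or `"high"`.
#' @param at_covariate_means predict at the weighted covariate means
#'   instead of averaging over the covariate distribution; for a linear
#'   model the two coincide, the flag exists for parity with
#'   predicted-margins software.
#' @return adjusted mean BMI (kg/m^2), or `NA` if the target group level
#'   was absent from the fitted model.
#' @export
marginal_mean <- function(fit, data, weights = data$survey_weight,
                          target = "overall", at_covariate_means = FALSE) {
  mf <- fit$model
  nd <- mf[setdiff(names(mf), c("bmi", "(weights)"))]
  if (target != "overall") {
    if (!"income_group" %in% names(nd) ||
        !target %in% levels(nd$income_group)) {
      return(NA_real_)                   # empty group: non-computable
    }
    nd$income_group <- factor(target, levels = levels(nd$income_group))
  }
  pred <- suppressWarnings(stats::predict(fit, newdata = nd))
  if (at_covariate_means) {
    # Linear model: prediction at weighted covariate means equals the
    # weighted mean of predictions; computed directly for clarity.
    return(stats::weighted.mean(pred, weights))
  }
  stats::weighted.mean(pred, weights)
}

#' Pool estimates over imputed datasets
#'
#' Rubin point pooling: the pooled estimate is the arithmetic mean of the
#' m per-dataset estimates; the between-imputation variance is recorded
#' for diagnostics. Any non-computable (NA) component makes the pooled
#' estimate non-computable.
#'
#' @param estimates numeric vector of per-dataset estimates.
#' @return list with `estimate`, `m`, `between_var`.
#' @export
pool_over_imputations <- function(estimates) {
  if (!length(estimates)) stop("no estimates to pool", call. = FALSE)
  if (anyNA(estimates)) {
    return(list(estimate = NA_real_, m = length(estimates),
                between_var = NA_real_))
  }
  list(estimate = mean(estimates), m = length(estimates),
       between_var = if (length(estimates) > 1) stats::var(estimates) else 0)
}

#' Adjusted mean BMI by state and income group, pooled over imputations
#'
#' Runs, for each completed dataset of an imputed stack: income-group
#' classification under both schemes, the adjustment model per scheme, and
#' marginal means overall and per group; then pools each estimand over the
#' m datasets. The state-average BMI used as the RHWDI reference is the
#' overall marginal mean from the same model.
#'
#' @param stack an [impute_chained()] result for one state.
#' @param guidelines poverty-guideline table.
#' @param weighted_p75 survey-weighted 75th percentile for the RHWDI cut
#'   point (default unweighted).
#' @param at_covariate_means passed to [marginal_mean()].
#' @param crude skip the adjustment model and use survey-weighted raw group
#'   means (default `FALSE`: model-adjusted means).
#' @return data.frame with one row per (scheme, group in overall/low/
#'   middle/high): columns `state`, `scheme`, `group`, `adjusted_mean`,
#'   `weighted_n`, `unweighted_n` (mean over datasets), `m_pooled_over`,
#'   `between_var`.
#' @export
state_group_means <- function(stack, guidelines, weighted_p75 = FALSE,
                              at_covariate_means = FALSE, crude = FALSE) {
  if (!inherits(stack, "hwd_imputed_stack")) {
    stop("`stack` must come from impute_chained()", call. = FALSE)
  }
  schemes <- c("rhwdi", "hwdi")
  groups <- c("overall", "low", "middle", "high")
  acc <- array(NA_real_, dim = c(stack$m, length(schemes), length(groups)),
               dimnames = list(NULL, schemes, groups))
  wn <- un <- array(0, dim = dim(acc), dimnames = dimnames(acc))
  for (i in seq_len(stack$m)) {
    d <- classify_income_groups(stack$datasets[[i]], guidelines,
                                weighted_p75 = weighted_p75)
    for (sc in schemes) {
      fit <- if (!crude) fit_bmi_model(d, sc)
      gcol <- d[[paste0(sc, "_group")]]
      for (g in groups) {
        acc[i, sc, g] <- if (crude) {
          in_g <- if (g == "overall") rep(TRUE, nrow(d)) else gcol == g
          if (any(in_g)) {
            stats::weighted.mean(d$bmi[in_g], d$survey_weight[in_g])
          } else NA_real_
        } else {
          marginal_mean(fit, d, d$survey_weight, g,
                        at_covariate_means = at_covariate_means)
        }
        in_g <- if (g == "overall") rep(TRUE, nrow(d)) else gcol == g
        wn[i, sc, g] <- sum(d$survey_weight[in_g])
        un[i, sc, g] <- sum(in_g)
      }
    }
  }
  rows <- expand.grid(group = groups, scheme = schemes,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    sc <- rows$scheme[r]; g <- rows$group[r]
    pooled <- pool_over_imputations(acc[, sc, g])
    data.frame(state = stack$state, scheme = sc, group = g,
               adjusted_mean = pooled$estimate,
               weighted_n = mean(wn[, sc, g]),
               unweighted_n = mean(un[, sc, g]),
               m_pooled_over = pooled$m,
               between_var = pooled$between_var)
  }))
  rownames(out) <- NULL
  out
}
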