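# Multiple imputation by chained equations, run separately per state.
#
# Variable-type methods follow the survey-analysis convention: continuous
# variables (bmi, n_children, n_adults) by Bayesian linear regression,
# ordinal variables (education, income_category) by predictive mean
# matching, the dichotomous variable (sex) by logistic regression.
# Race/ethnicity is never imputed: records missing it are case-wise
# deleted before imputation. The survey weight enters every imputation
# model as a *predictor* (not as a case weight).

.IMPUTABLE <- list(
  bmi = "linear", n_children = "linear", n_adults = "linear",
  education = "pmm", income_category = "pmm", sex = "logistic"
)

#' Imputation specification
#'
#' @param m_datasets number of completed datasets (default 20).
#' @param cycles_per_dataset chained-equation cycles per dataset
#'   (default 10, the common burn-in).
#' @param pmm_donor_count donors per predictive-mean-matching draw
#'   (default 5, the conventional choice).
#' @param include_weight_as_predictor include the survey weight as a
#'   predictor in every imputation model (default `TRUE`).
#' @param min_complete minimum observed cases required per modelled
#'   variable; below it the state is unimputable.
#' @param seed master integer seed; per-dataset seeds are derived from it
#'   by fixed offsets.
#' @return object of class `hwd_imputation_spec`.
#' @export
imputation_spec <- function(m_datasets = 20, cycles_per_dataset = 10,
                            pmm_donor_count = 5,
                            include_weight_as_predictor = TRUE,
                            min_complete = 10, seed = 1L) {
  structure(list(
    m_datasets = as_count(m_datasets, "m_datasets"),
    cycles_per_dataset = as_count(cycles_per_dataset, "cycles_per_dataset"),
    pmm_donor_count = as_count(pmm_donor_count, "pmm_donor_count"),
    include_weight_as_predictor = isTRUE(include_weight_as_predictor),
    min_complete = as_count(min_complete, "min_complete", allow_zero = TRUE),
    seed = as_count(seed, "seed", allow_zero = TRUE)
  ), class = "hwd_imputation_spec")
}

unimputable <- function(state, msg) {
  stop(structure(class = c("hwd_unimputable", "error", "condition"),
                 list(message = sprintf("state %s unimputable: %s", state, msg),
                      call = NULL)))
}

#' Chained-equations multiple imputation for one state
#'
#' Produces `m` completed datasets. Each dataset starts from random draws
#' of observed values, then runs a fixed number of cycles; within a cycle,
#' variables are visited in ascending order of missingness (most missing
#' last), each regressed on all other analysis variables plus the survey
#' weight. Draws are stochastic: posterior coefficient + residual draws
#' for linear steps, a coefficient draw for logistic steps, donor draws
#' for PMM — so the m datasets differ wherever values were missing.
#' Observed values are never altered. Identical `(records, spec)` yields
#' an identical stack. Imputed household counts are rounded to the nearest
#' non-negative integer.
#'
#' @param records one state's post-exclusion microdata.
#' @param spec an [imputation_spec()].
#' @return object of class `hwd_imputed_stack`: list with `datasets`
#'   (list of m completed data.frames), `state`, `m`, `seeds` (per-dataset
#'   seed trail), `n_casewise_deleted`.
#' @export
impute_chained <- function(records, spec = imputation_spec()) {
  stopifnot_microdata(records)
  state <- unique(records$state)
  if (length(state) != 1) {
    stop("impute_chained() operates on a single state", call. = FALSE)
  }

  # Case-wise deletion: race/ethnicity is not imputed; age and the survey
  # weight are required as predictors and are never missing in BRFSS-style
  # input (age is pre-imputed upstream by the data provider).
  complete_req <- !is.na(records$race_ethnicity) & !is.na(records$age_category) &
    !is.na(records$survey_weight)
  n_deleted <- sum(!complete_req)
  if (n_deleted > 0) {
    hwd_log("INFO", "imputation", "state %s: %d records case-wise deleted",
            state, n_deleted)
  }
  dat <- records[complete_req, , drop = FALSE]
  rownames(dat) <- NULL
  if (nrow(dat) == 0) unimputable(state, "no records after case-wise deletion")

  vars <- names(.IMPUTABLE)
  n_miss <- vapply(vars, function(v) sum(is.na(dat[[v]])), 0L)
  targets <- vars[n_miss > 0]
  for (v in targets) {
    n_obs <- sum(!is.na(dat[[v]]))
    if (n_obs == 0) unimputable(state, sprintf("no observed values for %s", v))
    if (n_obs < spec$min_complete) {
      unimputable(state, sprintf("only %d observed values for %s (minimum %d)",
                                 n_obs, v, spec$min_complete))
    }
  }
  # Visit order: ascending missingness so the best-observed variables
  # stabilise first; ties resolved by the fixed variable order above.
  targets <- targets[order(n_miss[targets], match(targets, vars))]

  seeds <- vapply(seq_len(spec$m_datasets),
                  function(m) derive_seed(spec$seed, m), integer(1))
  datasets <- lapply(seq_len(spec$m_datasets), function(m) {
    with_seed(seeds[m], impute_once(dat, targets, spec))
  })
  structure(list(datasets = datasets, state = state, m = spec$m_datasets,
                 seeds = seeds, n_casewise_deleted = n_deleted),
            class = "hwd_imputed_stack")
}

impute_once <- function(dat, targets, spec) {
  if (!length(targets)) return(dat)
  filled <- dat
  miss_idx <- lapply(targets, function(v) which(is.na(dat[[v]])))
  names(miss_idx) <- targets
  # Initialise by random draws from each variable's observed values.
  for (v in targets) {
    obs <- dat[[v]][!is.na(dat[[v]])]
    filled[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                         replace = TRUE)
  }
  for (cycle in seq_len(spec$cycles_per_dataset)) {
    for (v in targets) {
      idx <- miss_idx[[v]]
      X <- imputation_design(filled, v, spec$include_weight_as_predictor)
      y <- dat[[v]]                      # observed values only, never drifted
      obs <- which(!is.na(y))
      method <- .IMPUTABLE[[v]]
      imp <- switch(method,
        linear = norm_draw_impute(X[obs, , drop = FALSE], y[obs],
                                  X[idx, , drop = FALSE]),
        pmm = {
          k <- min(spec$pmm_donor_count, length(obs))
          pmm_impute(X[obs, , drop = FALSE], y[obs],
                     X[idx, , drop = FALSE], k)
        },
        logistic = logistic_draw_impute(X[obs, , drop = FALSE], y[obs],
                                        X[idx, , drop = FALSE])
      )
      if (v %in% c("n_adults", "n_children")) {
        imp <- pmax(round(imp), 0)       # counts: non-negative integers
      }
      filled[[v]][idx] <- imp
    }
  }
  filled
}

# Design matrix for imputing `target`: all other analysis variables plus
# (optionally) the survey weight. Age, race and sex enter as factors;
# ordinal variables and counts as numeric.
imputation_design <- function(filled, target, include_weight) {
  preds <- setdiff(c("age_category", "sex", "race_ethnicity", "education",
                     "income_category", "n_adults", "n_children", "bmi"),
                   target)
  cols <- list(`(Intercept)` = rep(1, nrow(filled)))
  for (v in preds) {
    x <- filled[[v]]
    if (v %in% c("age_category", "race_ethnicity", "sex")) {
      f <- factor(x)
      if (nlevels(f) > 1) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(v, levels(f)[-1])
        for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
      }
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  if (include_weight) cols[["survey_weight"]] <- filled$survey_weight
  do.call(cbind, cols)
}

# Drop linearly dependent columns via pivoted QR; returns kept indices.
full_rank_columns <- function(X) {
  qx <- qr(X)
  sort(qx$pivot[seq_len(qx$rank)])
}

# Bayesian linear-regression imputation: draw sigma^2 from its scaled
# inverse-chi-square posterior, beta from N(betahat, sigma^2 (X'X)^-1),
# then predicted mean + residual noise for each missing case.
norm_draw_impute <- function(X_obs, y_obs, X_mis) {
  keep <- full_rank_columns(X_obs)
  X <- X_obs[, keep, drop = FALSE]
  fit <- stats::lm.fit(X, y_obs)
  betahat <- fit$coefficients
  dfres <- max(length(y_obs) - ncol(X), 1)
  sigma2 <- sum(fit$residuals^2) / stats::rchisq(1, dfres)
  V <- chol2inv(chol(crossprod(X) + diag(1e-10, ncol(X))))
  beta <- betahat + drop(t(chol(V)) %*% stats::rnorm(ncol(X))) * sqrt(sigma2)
  drop(X_mis[, keep, drop = FALSE] %*% beta) +
    stats::rnorm(nrow(X_mis), 0, sqrt(sigma2))
}

# Logistic-regression imputation with a coefficient draw; falls back to
# observed-frequency draws under separation or non-convergence.
logistic_draw_impute <- function(X_obs, y_obs, X_mis) {
  lv <- sort(unique(y_obs))
  if (length(lv) == 1) return(rep(lv, nrow(X_mis)))
  y01 <- as.integer(y_obs == lv[2])
  keep <- full_rank_columns(X_obs)
  X <- X_obs[, keep, drop = FALSE]
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y01, family = stats::binomial())),
    error = function(e) NULL)
  separated <- is.null(fit) || !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (separated) {
    warning("logistic imputation step did not converge; falling back to ",
            "observed-frequency draws", call. = FALSE)
    p <- mean(y01)
    draw <- stats::rbinom(nrow(X_mis), 1, p)
    return(lv[draw + 1L])
  }
  w <- fit$fitted.values * (1 - fit$fitted.values)
  V <- chol2inv(chol(crossprod(X * sqrt(w)) + diag(1e-10, ncol(X))))
  beta <- fit$coefficients + drop(t(chol(V)) %*% stats::rnorm(ncol(X)))
  p <- stats::plogis(drop(X_mis[, keep, drop = FALSE] %*% beta))
  lv[stats::rbinom(nrow(X_mis), 1, p) + 1L]
}

#' Donor sets for predictive mean matching
#'
#' For each missing case, finds the `donor_count` observed cases whose
#' predicted means are nearest the missing case's predicted mean; distance
#' ties are broken by lowest observed-record index.
#'
#' @param pred_obs predicted means of the observed cases.
#' @param pred_mis predicted means of the missing cases.
#' @param donor_count donors per missing case.
#' @return integer matrix, one row per missing case, columns indexing into
#'   the observed cases.
#' @export
pmm_match <- function(pred_obs, pred_mis, donor_count) {
  if (donor_count < 1) stop("donor_count must be >= 1", call. = FALSE)
  if (donor_count > length(pred_obs)) {
    stop("donor_count exceeds number of observed cases", call. = FALSE)
  }
  t(vapply(pred_mis, function(p) {
    d <- abs(pred_obs - p)
    order(d, seq_along(d))[seq_len(donor_count)]
  }, integer(donor_count)))
}

pmm_impute <- function(X_obs, y_obs, X_mis, donor_count) {
  keep <- full_rank_columns(X_obs)
  X <- X_obs[, keep, drop = FALSE]
  betahat <- stats::lm.fit(X, y_obs)$coefficients
  pred_obs <- drop(X %*% betahat)
  pred_mis <- drop(X_mis[, keep, drop = FALSE] %*% betahat)
  donors <- pmm_match(pred_obs, pred_mis, donor_count)
  picked <- donors[cbind(seq_len(nrow(donors)),
                         sample.int(donor_count, nrow(donors), replace = TRUE))]
  y_obs[picked]
}

#' One predictive-mean-matching imputation step
#'
#' Standalone PMM: regresses the observed part of `target` on the
#' predictors, predicts the mean for every case, and fills each missing
#' entry with the observed value of one donor drawn uniformly from its
#' [pmm_match()] donor set. Imputed values are therefore always members of
#' the observed value set. If fewer observed cases than `donor_count`
#' exist, the donor count is lowered to what is available (with a warning).
#'
#' @param target numeric vector with `NA`s to fill.
#' @param predictors numeric matrix or data.frame of predictors (same row
#'   count as `target`); an intercept is added.
#' @param donor_count requested donors per missing case.
#' @param seed integer seed for the donor draws.
#' @return `target` with missing entries filled.
#' @export
pmm_step <- function(target, predictors, donor_count = 5, seed = 1L) {
  predictors <- as.matrix(predictors)
  if (nrow(predictors) != length(target)) {
    stop("`predictors` must have one row per target value", call. = FALSE)
  }
  obs <- which(!is.na(target))
  mis <- which(is.na(target))
  if (!length(obs)) stop("no observed cases to match against", call. = FALSE)
  if (!length(mis)) return(target)
  if (donor_count > length(obs)) {
    warning(sprintf("donor_count lowered from %d to %d (observed cases)",
                    donor_count, length(obs)), call. = FALSE)
    donor_count <- length(obs)
  }
  X <- cbind(`(Intercept)` = 1, predictors)
  with_seed(seed, {
    target[mis] <- pmm_impute(X[obs, , drop = FALSE], target[obs],
                              X[mis, , drop = FALSE], donor_count)
    target
  })
}
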