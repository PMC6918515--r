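#' Configuration for the BRFSS-like microdata generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_population()]. Defaults emulate the 2016 BRFSS analysis sample:
#' eight ordinal household-income categories with a right-heavy distribution
#' (34.2% in the top, >= $75,000 category), five age bands covering 18-64,
#' near-even sex split (50.8% female), six race/ethnicity groups, four
#' education levels, and a continuous BMI centred so the weighted population
#' mean is approximately 28.2 kg/m^2.
#'
#' BMI is generated directly on the continuous scale as
#' `bmi_base(state) + gradient(income group) + covariate effects + N(0, sd)`;
#' no height/weight simulation is attempted since BMI is the only
#' anthropometric quantity used downstream. The income group that receives
#' the gradient is the *fixed-dollar* low/middle/high classification
#' (categories 1-5 / 6-7 / 8), so the injected effect is known without
#' reference to any simulated poverty ratio.
#'
#' @param states character vector of state labels.
#' @param n_per_state respondents per state (>= 0).
#' @param income_category_probs probabilities for the 8 ordinal income
#'   categories; a single vector applied to every state, or a named list of
#'   per-state vectors.
#' @param bmi_base baseline mean BMI (kg/m^2); scalar or named per-state
#'   vector.
#' @param bmi_income_gradient additive BMI effect (kg/m^2) for the
#'   fixed-dollar low/middle/high income groups, in that order.
#' @param covariate_margins named list with probability vectors `age`
#'   (5 levels), `sex` (2: male, female), `race_ethnicity` (6), `education`
#'   (4).
#' @param covariate_bmi_effects named list of additive kg/m^2 effects per
#'   covariate level, same shapes as `covariate_margins`; defaults to zeros.
#' @param bmi_noise_sd residual BMI standard deviation (kg/m^2, >= 0).
#' @param household_size_dist data.frame with columns `n_adults`,
#'   `n_children`, `prob` describing the joint household-composition
#'   distribution.
#' @param weight_dispersion log-scale standard deviation of the log-normal
#'   survey weights (> 0); weights are normalised to mean 1 within state.
#' @param pregnancy_rate probability of pregnancy among female respondents.
#' @param seed integer RNG seed.
#' @return object of class `hwd_generator_config`.
#' @seealso [generate_population()], [inject_missingness()]
#' @export
generator_config <- function(states = paste0("State_", LETTERS[1:5]),
                             n_per_state = 2000,
                             income_category_probs =
                               c(6.2, 5.1, 7.6, 8.9, 9.8, 12.9, 14.7, 34.2) / 99.4,
                             bmi_base = 27.5,
                             bmi_income_gradient = c(low = 1.5, middle = 0.5, high = 0),
                             covariate_margins = list(
                               age = c(15.2, 21.3, 20.6, 21.6, 21.3) / 100,
                               sex = c(49.2, 50.8) / 100,
                               race_ethnicity = c(58.5, 12.2, 5.5, 1.6, 1.6, 18.6) / 98.0,
                               education = c(13.4, 27.7, 31.5, 27.3) / 99.9
                             ),
                             covariate_bmi_effects = NULL,
                             bmi_noise_sd = 6,
                             household_size_dist = default_household_dist(),
                             weight_dispersion = 0.5,
                             pregnancy_rate = 0.03,
                             seed = 1L) {
  if (!is.character(states) || !length(states) || anyDuplicated(states)) {
    stop("`states` must be a non-empty character vector without duplicates",
         call. = FALSE)
  }
  n_per_state <- as_count(n_per_state, "n_per_state", allow_zero = TRUE)

  income_category_probs <- per_state_probs(income_category_probs, states,
                                           "income_category_probs", 8)
  bmi_base <- per_state_scalar(bmi_base, states, "bmi_base")

  if (length(bmi_income_gradient) != 3) {
    stop("`bmi_income_gradient` must give (low, middle, high) effects",
         call. = FALSE)
  }
  bmi_income_gradient <- stats::setNames(as.numeric(bmi_income_gradient),
                                         c("low", "middle", "high"))

  lvl <- c(age = 5L, sex = 2L, race_ethnicity = 6L, education = 4L)
  for (v in names(lvl)) {
    check_prob_vector(covariate_margins[[v]],
                      paste0("covariate_margins$", v), lvl[[v]])
  }
  if (is.null(covariate_bmi_effects)) {
    covariate_bmi_effects <- lapply(lvl, function(k) rep(0, k))
  }
  for (v in names(lvl)) {
    eff <- covariate_bmi_effects[[v]]
    if (is.null(eff)) eff <- rep(0, lvl[[v]])
    if (length(eff) != lvl[[v]] || !is.numeric(eff)) {
      stop(sprintf("`covariate_bmi_effects$%s` must be numeric of length %d",
                   v, lvl[[v]]), call. = FALSE)
    }
    covariate_bmi_effects[[v]] <- as.numeric(eff)
  }

  if (!is.numeric(bmi_noise_sd) || bmi_noise_sd < 0) {
    stop("`bmi_noise_sd` must be >= 0", call. = FALSE)
  }
  if (!is.data.frame(household_size_dist) ||
      !all(c("n_adults", "n_children", "prob") %in% names(household_size_dist))) {
    stop("`household_size_dist` needs columns n_adults, n_children, prob",
         call. = FALSE)
  }
  check_prob_vector(household_size_dist$prob, "household_size_dist$prob")
  if (any(household_size_dist$n_adults + household_size_dist$n_children < 1)) {
    stop("household sizes must be >= 1", call. = FALSE)
  }
  if (!is.numeric(weight_dispersion) || weight_dispersion <= 0) {
    stop("`weight_dispersion` must be > 0", call. = FALSE)
  }
  if (pregnancy_rate < 0 || pregnancy_rate > 1) {
    stop("`pregnancy_rate` must be in [0, 1]", call. = FALSE)
  }

  structure(list(
    states = states, n_per_state = n_per_state,
    income_category_probs = income_category_probs,
    bmi_base = bmi_base, bmi_income_gradient = bmi_income_gradient,
    covariate_margins = covariate_margins,
    covariate_bmi_effects = covariate_bmi_effects,
    bmi_noise_sd = as.numeric(bmi_noise_sd),
    household_size_dist = household_size_dist,
    weight_dispersion = as.numeric(weight_dispersion),
    pregnancy_rate = as.numeric(pregnancy_rate),
    seed = as_count(seed, "seed", allow_zero = TRUE)
  ), class = "hwd_generator_config")
}

#' Default joint household-composition distribution
#'
#' Independent product of adults in {1,2,3} and children in {0,1,2,3} with
#' marginal weights typical of U.S. adult households.
#'
#' @return data.frame with columns `n_adults`, `n_children`, `prob`.
#' @export
default_household_dist <- function() {
  grid <- expand.grid(n_adults = 1:3, n_children = 0:3)
  p_a <- c(0.30, 0.55, 0.15)[grid$n_adults]
  p_c <- c(0.48, 0.20, 0.22, 0.10)[grid$n_children + 1L]
  data.frame(n_adults = grid$n_adults, n_children = grid$n_children,
             prob = p_a * p_c)
}

per_state_probs <- function(p, states, name, n_levels) {
  if (is.list(p)) {
    missing_states <- setdiff(states, names(p))
    if (length(missing_states)) {
      stop(sprintf("`%s` lacks entries for: %s", name,
                   paste(missing_states, collapse = ", ")), call. = FALSE)
    }
    for (s in states) check_prob_vector(p[[s]], sprintf("%s[%s]", name, s), n_levels)
    p[states]
  } else {
    check_prob_vector(p, name, n_levels)
    stats::setNames(rep(list(as.numeric(p)), length(states)), states)
  }
}

per_state_scalar <- function(x, states, name) {
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  if (length(x) == 1) return(stats::setNames(rep(as.numeric(x), length(states)), states))
  if (is.null(names(x)) || !all(states %in% names(x))) {
    stop(sprintf("`%s` must be scalar or named per state", name), call. = FALSE)
  }
  stats::setNames(as.numeric(x[states]), states)
}

#' Generate a complete synthetic survey population
#'
#' Draws `n_per_state` complete respondent records per state according to the
#' configuration. All categorical variables are sampled from the configured
#' margins, BMI follows the additive model described in
#' [generator_config()], survey weights are log-normal normalised to mean 1
#' within state, and pregnancy occurs only among female respondents.
#' Identical `(config)` including its seed yields bitwise-identical output.
#'
#' @param config a [generator_config()] object.
#' @return data.frame of complete respondent microdata with columns
#'   `state`, `age_category`, `sex` (1 = male, 2 = female),
#'   `race_ethnicity`, `education`, `income_category`, `n_adults`,
#'   `n_children`, `bmi`, `pregnant` (0/1), `survey_weight`.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "hwd_generator_config")) {
    stop("`config` must come from generator_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    out <- lapply(config$states, function(s) generate_state(config, s))
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  })
}

generate_state <- function(config, state) {
  n <- config$n_per_state
  if (n == 0) {
    return(empty_microdata())
  }
  m <- config$covariate_margins
  income_category <- sample.int(8L, n, replace = TRUE,
                                prob = config$income_category_probs[[state]])
  age_category <- sample.int(5L, n, replace = TRUE, prob = m$age)
  sex <- sample.int(2L, n, replace = TRUE, prob = m$sex)
  race_ethnicity <- sample.int(6L, n, replace = TRUE, prob = m$race_ethnicity)
  education <- sample.int(4L, n, replace = TRUE, prob = m$education)

  hh_idx <- sample.int(nrow(config$household_size_dist), n, replace = TRUE,
                       prob = config$household_size_dist$prob)
  n_adults <- as.integer(config$household_size_dist$n_adults[hh_idx])
  n_children <- as.integer(config$household_size_dist$n_children[hh_idx])

  grad <- config$bmi_income_gradient[hwdi_income_group(income_category)]
  eff <- config$covariate_bmi_effects
  bmi <- config$bmi_base[[state]] + as.numeric(grad) +
    eff$age[age_category] + eff$sex[sex] + eff$race_ethnicity[race_ethnicity] +
    eff$education[education] +
    stats::rnorm(n, 0, config$bmi_noise_sd)

  pregnant <- integer(n)
  female <- sex == 2L
  pregnant[female] <- stats::rbinom(sum(female), 1L, config$pregnancy_rate)

  w <- stats::rlnorm(n, meanlog = 0, sdlog = config$weight_dispersion)
  w <- w / mean(w)  # mean-1 normalisation within state

  data.frame(state = state, age_category = age_category, sex = sex,
             race_ethnicity = race_ethnicity, education = education,
             income_category = income_category, n_adults = n_adults,
             n_children = n_children, bmi = bmi, pregnant = pregnant,
             survey_weight = w)
}

empty_microdata <- function() {
  data.frame(state = character(), age_category = integer(), sex = integer(),
             race_ethnicity = integer(), education = integer(),
             income_category = integer(), n_adults = integer(),
             n_children = integer(), bmi = numeric(), pregnant = integer(),
             survey_weight = numeric())
}

#' Missingness specification
#'
#' @param rates named numeric vector of per-variable missingness rates in
#'   `[0, 1]`; names must be microdata columns.
#' @param mechanism `"MCAR"` (completely at random) or `"MAR-on-weight"`
#'   (probability of missingness monotone increasing in the survey weight,
#'   calibrated so the average rate equals the requested rate).
#' @param seed integer RNG seed.
#' @return object of class `hwd_missingness_spec`.
#' @export
missingness_spec <- function(rates, mechanism = c("MCAR", "MAR-on-weight"),
                             seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(rates) || is.null(names(rates)) || any(names(rates) == "")) {
    stop("`rates` must be a named numeric vector", call. = FALSE)
  }
  if (any(rates < 0 | rates > 1)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(names(rates), MICRODATA_COLUMNS)
  if (length(bad)) {
    stop("unknown variable(s) in `rates`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(rates = rates, mechanism = mechanism,
                 seed = as_count(seed, "seed", allow_zero = TRUE)),
            class = "hwd_missingness_spec")
}

#' Mask values in complete microdata
#'
#' Sets targeted fields to `NA` according to the specification; values are
#' never altered, only masked. Under `"MAR-on-weight"` the per-record
#' masking probability is `plogis(a + z)` where `z` is the standardised log
#' survey weight and the intercept `a` is solved so the mean probability
#' equals the requested rate — missingness is then monotone increasing in
#' the weight while the expected overall rate is preserved.
#'
#' @param records complete microdata data.frame.
#' @param spec a [missingness_spec()] object.
#' @return `records` with `NA` injected.
#' @export
inject_missingness <- function(records, spec) {
  stopifnot_microdata(records)
  if (!inherits(spec, "hwd_missingness_spec")) {
    stop("`spec` must come from missingness_spec()", call. = FALSE)
  }
  n <- nrow(records)
  if (n == 0) return(records)
  with_seed(spec$seed, {
    for (v in names(spec$rates)) {
      r <- spec$rates[[v]]
      if (r == 0) next
      if (r == 1) {
        records[[v]] <- replace(records[[v]], TRUE, NA)
        next
      }
      p <- if (spec$mechanism == "MCAR") {
        rep(r, n)
      } else {
        mar_on_weight_probs(records$survey_weight, r)
      }
      mask <- stats::runif(n) < p
      records[[v]][mask] <- NA
    }
    records
  })
}

# Logistic-in-log-weight probabilities calibrated to a target mean rate.
mar_on_weight_probs <- function(weights, rate) {
  lw <- log(weights)
  z <- if (stats::sd(lw) > 0) (lw - mean(lw)) / stats::sd(lw) else rep(0, length(lw))
  a <- stats::uniroot(function(a) mean(stats::plogis(a + z)) - rate,
                      interval = c(-40, 40), tol = 1e-10)$root
  stats::plogis(a + z)
}
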