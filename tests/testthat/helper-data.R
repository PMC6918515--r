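# Shared fixtures, built in code.

# Small complete microdata table with hand-controllable fields.
make_microdata <- function(n = 10, state = "S1", bmi = 27, pregnant = 0,
                           age_category = 2, income_category = NULL,
                           seed = 99) {
  set.seed(seed)
  data.frame(
    state = state,
    age_category = rep_len(age_category, n),
    sex = rep_len(c(1L, 2L), n),
    race_ethnicity = rep_len(1:3, n),
    education = rep_len(1:4, n),
    income_category = if (is.null(income_category)) rep_len(1:8, n) else
      rep_len(income_category, n),
    n_adults = rep_len(c(1L, 2L), n),
    n_children = rep_len(c(0L, 1L), n),
    bmi = rep_len(bmi, n) + 0,
    pregnant = rep_len(pregnant, n),
    survey_weight = rep(1, n)
  )
}

# Generator config with uniform demographic margins: no sparse
# income-by-race cells at desk-scale n, so eligibility screening never
# censors states in tests that are not about eligibility.
test_gen_config <- function(states = c("Alpha", "Beta"), n_per_state = 500,
                            seed = 7, ...) {
  generator_config(
    states = states, n_per_state = n_per_state,
    income_category_probs = rep(1 / 8, 8),
    covariate_margins = list(age = rep(0.2, 5), sex = c(0.5, 0.5),
                             race_ethnicity = c(0.4, 0.3, 0.3, 0, 0, 0),
                             education = rep(0.25, 4)),
    seed = seed, ...)
}

# Synthetic guideline table used by unit tests (never the packaged HHS
# dollar values).
toy_guidelines <- function(base = 10000, increment = 5000) {
  structure(data.frame(
    region = c("contiguous_and_DC", "alaska", "hawaii"),
    year = 2016,
    base_dollars = c(base, base * 1.25, base * 1.15),
    increment_dollars = c(increment, increment * 1.25, increment * 1.15)
  ), class = c("hwd_guideline_table", "data.frame"))
}
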