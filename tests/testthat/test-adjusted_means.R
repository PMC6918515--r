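with_hwdi_groups <- function(pop) {
  pop$hwdi_group <- hwdi_income_group(pop$income_category)
  pop
}

test_that("equal weights reproduce the unweighted regression exactly", {
  pop <- with_hwdi_groups(generate_population(
    test_gen_config(states = "One", n_per_state = 400)))
  pop$survey_weight <- rep(2.5, nrow(pop))
  fit_w <- fit_bmi_model(pop, "hwdi")
  fit_u <- lm(bmi ~ factor(age_category) + factor(race_ethnicity) +
                factor(sex) + factor(education) +
                factor(hwdi_group, levels = c("low", "middle", "high")),
              data = pop)
  expect_equal(unname(coef(fit_w)), unname(coef(fit_u)), tolerance = 1e-10)
})

test_that("single-level factors are dropped and the fit proceeds", {
  pop <- with_hwdi_groups(generate_population(
    test_gen_config(states = "One", n_per_state = 120)))
  pop$sex <- 1L  # all male
  pop$pregnant <- 0L
  fit <- fit_bmi_model(pop, "hwdi")
  expect_false(any(grepl("sex", names(coef(fit)))))
  expect_true(is.finite(marginal_mean(fit, pop, target = "low")))
})

test_that("overall marginal mean equals the weighted raw mean of BMI", {
  pop <- with_hwdi_groups(generate_population(
    test_gen_config(states = "One", n_per_state = 300, seed = 12)))
  fit <- fit_bmi_model(pop, "hwdi")
  expect_equal(marginal_mean(fit, pop, target = "overall"),
               weighted.mean(pop$bmi, pop$survey_weight), tolerance = 1e-10)
  # intercept-only model: marginal mean is exactly the weighted mean
  pop1 <- pop
  pop1$age_category <- 1L; pop1$race_ethnicity <- 1L; pop1$sex <- 1L
  pop1$education <- 1L; pop1$hwdi_group <- "low"
  fit1 <- fit_bmi_model(pop1, "hwdi")
  expect_equal(marginal_mean(fit1, pop1, target = "overall"),
               weighted.mean(pop1$bmi, pop1$survey_weight), tolerance = 1e-12)
})

test_that("setting all respondents to group g reproduces the linear
           prediction identity", {
  pop <- with_hwdi_groups(generate_population(
    test_gen_config(states = "One", n_per_state = 250, seed = 4)))
  fit <- fit_bmi_model(pop, "hwdi")
  cf <- coef(fit)
  w <- pop$survey_weight
  # manual: intercept + group effect + weighted covariate means x coefs
  mm <- model.matrix(fit)
  base_cols <- !grepl("income_group", colnames(mm))
  manual <- sum(colSums(mm[, base_cols, drop = FALSE] * w) / sum(w) *
                  cf[base_cols]) + unname(cf["income_grouphigh"])
  expect_equal(marginal_mean(fit, pop, target = "high"), manual,
               tolerance = 1e-10)
})

test_that("income-group coefficients recover the generator gradient when
           covariate effects are zero", {
  cfg <- test_gen_config(states = "One", n_per_state = 20000, seed = 31,
                         bmi_income_gradient = c(2, 0, 0), bmi_noise_sd = 3)
  pop <- with_hwdi_groups(generate_population(cfg))
  fit <- fit_bmi_model(pop, "hwdi")
  grp <- pop$hwdi_group
  mc_se <- 3 * sqrt(1 / sum(grp == "low") + 1 / sum(grp == "high"))
  expect_lt(abs(unname(coef(fit)["income_grouphigh"]) - (-2)), 3 * mc_se)
  # adjusted group means agree with weighted raw group means (covariates
  # are identically distributed across income groups by construction)
  raw_low <- weighted.mean(pop$bmi[grp == "low"],
                           pop$survey_weight[grp == "low"])
  expect_lt(abs(marginal_mean(fit, pop, target = "low") - raw_low),
            3 * mc_se)
})

test_that("empty target group is non-computable and propagates through
           pooling", {
  pop <- with_hwdi_groups(generate_population(
    test_gen_config(states = "One", n_per_state = 100)))
  pop$hwdi_group[pop$hwdi_group == "middle"] <- "low"
  fit <- fit_bmi_model(pop, "hwdi")
  expect_true(is.na(marginal_mean(fit, pop, target = "middle")))
  pooled <- pool_over_imputations(c(27, NA, 28))
  expect_true(is.na(pooled$estimate))
})

test_that("pooling is the arithmetic mean with between-variance recorded", {
  expect_equal(pool_over_imputations(c(27, 28))$estimate, 27.5)
  expect_equal(pool_over_imputations(rep(26.1, 5))$estimate, 26.1)
  expect_equal(pool_over_imputations(rep(26.1, 5))$between_var, 0)
  expect_equal(pool_over_imputations(c(27, 28))$between_var, 0.5)
  expect_error(pool_over_imputations(numeric()), "no estimates")
})

test_that("weight-scale invariance and record-order invariance of the
           pooled state-group means", {
  pop <- generate_population(test_gen_config(states = "One",
                                             n_per_state = 250, seed = 8))
  stack <- impute_chained(pop, imputation_spec(m_datasets = 2,
                                               cycles_per_dataset = 2,
                                               seed = 3))
  g <- toy_guidelines()
  m1 <- state_group_means(stack, g)
  stack_scaled <- stack
  stack_scaled$datasets <- lapply(stack$datasets, function(d) {
    d$survey_weight <- d$survey_weight * 17
    d
  })
  m2 <- state_group_means(stack_scaled, g)
  expect_equal(m1$adjusted_mean, m2$adjusted_mean, tolerance = 1e-9)

  perm <- sample(nrow(pop))
  stack_perm <- stack
  stack_perm$datasets <- lapply(stack$datasets, function(d) d[perm, ])
  m3 <- state_group_means(stack_perm, g)
  expect_equal(m1$adjusted_mean, m3$adjusted_mean, tolerance = 1e-9)
})

test_that("overall mean lies within the span of the group means; crude
           option returns weighted raw means", {
  pop <- generate_population(test_gen_config(states = "One",
                                             n_per_state = 400, seed = 19))
  stack <- impute_chained(pop, imputation_spec(m_datasets = 1))
  g <- toy_guidelines()
  m <- state_group_means(stack, g)
  for (sc in c("rhwdi", "hwdi")) {
    sub <- m[m$scheme == sc, ]
    grp <- sub$adjusted_mean[sub$group != "overall"]
    ov <- sub$adjusted_mean[sub$group == "overall"]
    expect_gte(ov, min(grp) - 1e-9)
    expect_lte(ov, max(grp) + 1e-9)
  }
  mc <- state_group_means(stack, g, crude = TRUE)
  d <- classify_income_groups(pop, g)
  lo <- d$hwdi_group == "low"
  expect_equal(mc$adjusted_mean[mc$scheme == "hwdi" & mc$group == "low"],
               weighted.mean(d$bmi[lo], d$survey_weight[lo]),
               tolerance = 1e-10)
})
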