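masked_state <- function(n = 300, seed = 21, rates = c(bmi = 0.2),
                         mechanism = "MCAR") {
  pop <- generate_population(test_gen_config(states = "One", n_per_state = n,
                                             seed = seed))
  list(complete = pop,
       masked = inject_missingness(pop, missingness_spec(rates, mechanism,
                                                         seed = seed + 1)))
}

test_that("input with no missing values passes through untouched", {
  pop <- generate_population(test_gen_config(states = "One", n_per_state = 80))
  stack <- impute_chained(pop, imputation_spec(m_datasets = 3,
                                               cycles_per_dataset = 2))
  expect_equal(stack$m, 3)
  for (d in stack$datasets) expect_identical(d, pop)
})

test_that("records missing race/ethnicity are case-wise deleted from every
           dataset; observed values are never altered", {
  ms <- masked_state(rates = c(bmi = 0.3, education = 0.2))
  dat <- ms$masked
  dat$race_ethnicity[1:10] <- NA
  stack <- impute_chained(dat, imputation_spec(m_datasets = 4,
                                               cycles_per_dataset = 3,
                                               seed = 5))
  expect_equal(stack$n_casewise_deleted, 10)
  kept <- dat[-(1:10), ]
  obs_bmi <- !is.na(kept$bmi)
  for (d in stack$datasets) {
    expect_equal(nrow(d), nrow(dat) - 10)
    expect_false(anyNA(d$bmi))
    expect_false(anyNA(d$education))
    expect_identical(d$bmi[obs_bmi], kept$bmi[obs_bmi])
    expect_identical(d$income_category, kept$income_category)
    # PMM keeps ordinal imputations inside the observed category range
    expect_true(all(d$education %in% unique(kept$education[!is.na(kept$education)])))
  }
})

test_that("identical seed gives an identical stack; datasets differ among
           themselves where values were imputed", {
  ms <- masked_state(rates = c(bmi = 0.25))
  spec <- imputation_spec(m_datasets = 3, cycles_per_dataset = 3, seed = 17)
  s1 <- impute_chained(ms$masked, spec)
  s2 <- impute_chained(ms$masked, spec)
  expect_identical(s1$datasets, s2$datasets)
  miss <- is.na(ms$masked$bmi)
  expect_false(identical(s1$datasets[[1]]$bmi[miss], s1$datasets[[2]]$bmi[miss]))
})

test_that("unimputable states are signalled as a typed condition", {
  pop <- generate_population(test_gen_config(states = "One", n_per_state = 40))
  pop$bmi <- NA_real_
  expect_error(impute_chained(pop, imputation_spec(m_datasets = 1)),
               class = "hwd_unimputable")
  pop2 <- generate_population(test_gen_config(states = "One", n_per_state = 40))
  pop2$bmi[1:35] <- NA   # 5 observed < min_complete 10
  expect_error(impute_chained(pop2, imputation_spec(m_datasets = 1)),
               class = "hwd_unimputable")
})

test_that("imputed household counts are non-negative integers", {
  ms <- masked_state(rates = c(n_adults = 0.3, n_children = 0.3), seed = 33)
  stack <- impute_chained(ms$masked, imputation_spec(m_datasets = 2,
                                                     cycles_per_dataset = 3,
                                                     seed = 2))
  for (d in stack$datasets) {
    expect_true(all(d$n_adults >= 0 & d$n_adults == round(d$n_adults)))
    expect_true(all(d$n_children >= 0 & d$n_children == round(d$n_children)))
  }
})

test_that("MCAR-masked BMI: pooled mean lands within 3 MC SEs of the
           complete-data mean (m = 20)", {
  ms <- masked_state(n = 2000, seed = 9, rates = c(bmi = 0.2))
  stack <- impute_chained(ms$masked, imputation_spec(m_datasets = 20,
                                                     cycles_per_dataset = 3,
                                                     seed = 11))
  pooled <- pool_over_imputations(
    vapply(stack$datasets, function(d) mean(d$bmi), 0))
  truth <- mean(ms$complete$bmi)
  mc_se <- sd(ms$complete$bmi) / sqrt(nrow(ms$complete))
  expect_lt(abs(pooled$estimate - truth), 3 * mc_se)
})

test_that("pmm_match donor sets match exhaustive nearest-neighbour search
           with index tie-breaking", {
  pred_obs <- c(1.0, 2.0, 2.0, 5.0, 9.0)
  pred_mis <- c(1.9, 6.8)
  donors <- pmm_match(pred_obs, pred_mis, 3)
  # case 1: distances 0.9, 0.1, 0.1, 3.1, 7.1 -> donors 2, 3 (tie by index), 1
  expect_equal(sort(donors[1, ]), c(1, 2, 3))
  expect_equal(donors[1, 1:2], c(2, 3))
  # case 2: distances 5.8, 4.8, 4.8, 1.8, 2.2 -> donors 4, 5, 2
  expect_equal(donors[2, ], c(4, 5, 2))

  brute <- function(po, p, k) {
    d <- abs(po - p)
    ord <- order(d, seq_along(po))
    ord[seq_len(k)]
  }
  set.seed(12)
  for (rep in 1:50) {
    po <- round(runif(sample(3:8, 1)), 2)
    p <- round(runif(1), 2)
    k <- sample(seq_along(po), 1)
    expect_equal(drop(pmm_match(po, p, k)), brute(po, p, k))
  }
})

test_that("pmm_step: imputed values are always observed values; a single
           observed case donates everywhere; donor count is lowered with a
           warning", {
  x <- c(10, NA, 30, NA, 50)
  pred <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  filled <- pmm_step(x, pred, donor_count = 2, seed = 3)
  expect_true(all(filled[c(2, 4)] %in% c(10, 30, 50)))
  expect_identical(filled[c(1, 3, 5)], c(10, 30, 50))

  one <- c(7, NA, NA)
  expect_warning(f1 <- pmm_step(one, matrix(1:3, ncol = 1), donor_count = 5),
                 "lowered")
  expect_equal(f1, c(7, 7, 7))
  expect_identical(pmm_step(c(1, 2), matrix(1:2, ncol = 1)), c(1, 2))
})

test_that("logistic step falls back to frequency draws under separation", {
  pop <- generate_population(test_gen_config(states = "One", n_per_state = 60,
                                             seed = 14))
  pop$pregnant <- 0L
  # make sex perfectly separable by bmi
  pop$bmi <- ifelse(pop$sex == 2, 40 + runif(60), 20 + runif(60))
  pop$sex[1:12] <- NA
  expect_warning(
    stack <- impute_chained(pop, imputation_spec(m_datasets = 1,
                                                 cycles_per_dataset = 1,
                                                 seed = 4)),
    "did not converge")
  expect_true(all(stack$datasets[[1]]$sex %in% 1:2))
})
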