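test_that("microdata round-trips through write/read", {
  pop <- generate_population(test_gen_config(n_per_state = 60))
  path <- withr::local_tempfile(fileext = ".csv")
  write_microdata(pop, path)
  back <- read_microdata(path)
  attr(back, "coercion_tally") <- NULL
  expect_equal(back, pop, tolerance = 1e-12)
})

test_that("unparseable and out-of-range cells become missing markers with
           a tally; schema errors name the column", {
  pop <- generate_population(test_gen_config(n_per_state = 10,
                                             states = "One"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_microdata(pop, path)
  lines <- readLines(path)
  lines[2] <- sub("^One,", "One,", lines[2])
  f <- strsplit(lines[2], ",")[[1]]
  f[9] <- "banana"       # bmi column
  f[4] <- "17"           # race out of range
  lines[2] <- paste(f, collapse = ",")
  writeLines(lines, path)
  expect_warning(back <- read_microdata(path), "coerced to missing")
  expect_true(is.na(back$bmi[1]))
  expect_true(is.na(back$race_ethnicity[1]))
  tally <- attr(back, "coercion_tally")
  expect_equal(unname(tally[["bmi"]]), 1)
  expect_equal(nrow(back), 10)   # row count preserved

  # header is matched case-insensitively
  lines[1] <- toupper(lines[1])
  writeLines(lines, path)
  expect_warning(back2 <- read_microdata(path), "coerced")
  expect_equal(nrow(back2), 10)

  # dropping a mandatory column is a schema error naming it
  no_state <- pop[setdiff(names(pop), "state")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(no_state, path2, row.names = FALSE)
  expect_error(read_microdata(path2), "state")
  expect_error(read_microdata("/nonexistent/file.csv"), "not found")
})

test_that("packaged index fixture loads and validates", {
  fx <- load_index_fixture()
  expect_equal(nrow(fx), 49)
  expect_false(any(fx$state %in% c("Michigan", "South Dakota")))
  expect_setequal(fx$rhwdi_rank, 1:49)
  expect_setequal(fx$hwdi_rank, 1:49)
})

test_that("compare_fixture on equal rank columns is perfect concordance", {
  fx <- load_index_fixture()
  fx$hwdi_rank <- fx$rhwdi_rank
  rep <- compare_fixture(fx)
  expect_equal(rep$rho, 1)
  expect_equal(rep$kappa, 1)
  expect_true(all(rep$diffs$diff == 0))
})

test_that("pipeline is deterministic and writes balanced, provenance-
           stamped outputs", {
  gcfg <- test_gen_config(states = c("Alpha", "Beta", "Gamma"),
                          n_per_state = 250)
  out1 <- withr::local_tempdir()
  cfg <- pipeline_config(
    input = gcfg, guidelines = toy_guidelines(),
    missingness = missingness_spec(c(bmi = 0.15)),
    imputation = imputation_spec(m_datasets = 2, cycles_per_dataset = 2),
    check_crosstab = FALSE,
    seed = 101, output_dir = out1, log_level = "ERROR")
  res1 <- run_pipeline(cfg)
  cfg2 <- cfg; cfg2$output_dir <- NULL
  res2 <- run_pipeline(cfg2)
  expect_identical(res1$index_table, res2$index_table)
  expect_equal(res1$concordance$rho, res2$concordance$rho)

  # outputs exist, carry the seed header, and the run log balances counts
  files <- c("index_table.csv", "adjusted_means.csv", "state_eligibility.csv",
             "exclusion_tally.csv", "concordance.txt", "rank_comparison.csv",
             "run_log.txt")
  for (f in files) expect_true(file.exists(file.path(out1, f)))
  header <- readLines(file.path(out1, "index_table.csv"), n = 1)
  expect_match(header, "seed=101")
  expect_equal(sum(res1$exclusion_tally), 750)

  idx <- utils::read.csv(file.path(out1, "index_table.csv"), comment.char = "#")
  expect_equal(idx$state, res1$index_table$state)
})

test_that("with complete data, m = 1 equals a many-imputation run
           (imputation is a no-op)", {
  gcfg <- test_gen_config(states = c("Alpha", "Beta", "Gamma"),
                          n_per_state = 200, seed = 13)
  base <- list(input = gcfg, guidelines = toy_guidelines(), seed = 7,
               check_crosstab = FALSE, log_level = "ERROR")
  r1 <- run_pipeline(do.call(pipeline_config, c(base, list(
    imputation = imputation_spec(m_datasets = 1)))))
  r20 <- run_pipeline(do.call(pipeline_config, c(base, list(
    imputation = imputation_spec(m_datasets = 5)))))
  expect_equal(r1$index_table, r20$index_table, tolerance = 1e-12)
})

test_that("pipeline RHWDI sign matches the generator construction", {
  gcfg <- test_gen_config(states = c("Alpha", "Beta"), n_per_state = 600,
                          seed = 23, bmi_income_gradient = c(3, 1, 0),
                          bmi_noise_sd = 2)
  res <- run_pipeline(pipeline_config(
    input = gcfg, guidelines = toy_guidelines(),
    imputation = imputation_spec(m_datasets = 1), seed = 5,
    check_crosstab = FALSE, log_level = "ERROR"))
  expect_true(all(res$index_table$rhwdi > 0))
  expect_true(all(res$index_table$hwdi > 0))
})

test_that("unimputable state is reported as dropped, not fatal", {
  gcfg <- test_gen_config(states = c("Alpha", "Beta", "Gamma", "Delta"),
                          n_per_state = 150, seed = 3)
  pop <- generate_population(gcfg)
  pop$bmi[pop$state == "Delta"] <- NA  # nothing to fit a BMI model on
  res <- run_pipeline(pipeline_config(
    input = pop, guidelines = toy_guidelines(),
    imputation = imputation_spec(m_datasets = 1),
    missing_threshold = 1, check_crosstab = FALSE, seed = 2,
    log_level = "ERROR"))
  expect_true("Delta" %in% res$dropped_states)
  expect_false("Delta" %in% res$index_table$state)
  expect_equal(sort(res$index_table$state), c("Alpha", "Beta", "Gamma"))
})

test_that("CLI: simulate writes microdata and compare-indices reports", {
  cfg_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(states = c("A", "B"), n_per_state = 30,
                            seed = 4),
                       cfg_path, auto_unbox = TRUE)
  out_csv <- withr::local_tempfile(fileext = ".csv")
  expect_output(hwdi_cli(c("simulate", "--config", cfg_path,
                           "--out", out_csv)),
                "wrote 60 records")
  expect_equal(nrow(read_microdata(out_csv)), 60)

  out_txt <- withr::local_tempfile(fileext = ".txt")
  expect_output(hwdi_cli(c("compare-indices", "--out", out_txt)),
                "Rank concordance over 49 states")
  expect_true(any(grepl("Spearman", readLines(out_txt))))
  expect_error(hwdi_cli("frobnicate"), "unknown verb")
})
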