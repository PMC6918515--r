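# File I/O, pipeline configuration and driver, the packaged printed index
# table, and a small command-line front end.

# Expected column types for microdata reading; the value range each cell
# must satisfy to be kept (out-of-range cells become missing markers).
# Age categories above 5 are deliberately *kept* so the over-65 exclusion
# can act on them downstream.
.MICRODATA_RULES <- list(
  state = list(type = "character"),
  age_category = list(type = "integer", min = 1),
  sex = list(type = "integer", min = 1, max = 2),
  race_ethnicity = list(type = "integer", min = 1, max = 6),
  education = list(type = "integer", min = 1, max = 4),
  income_category = list(type = "integer", min = 1, max = 8),
  n_adults = list(type = "integer", min = 0),
  n_children = list(type = "integer", min = 0),
  bmi = list(type = "numeric", min = 1e-9),
  pregnant = list(type = "flag"),
  survey_weight = list(type = "numeric", min = 1e-12)
)

#' Read respondent microdata from delimited text
#'
#' Comma-delimited, one row per respondent, header matched
#' case-insensitively against the standard schema. Empty strings are
#' missing. Unparseable or out-of-range cells become missing markers and
#' are tallied per column (logged as a warning); the row count is always
#' preserved.
#'
#' @param path CSV file path.
#' @return microdata data.frame; attribute `coercion_tally` counts cells
#'   turned into missing markers per column.
#' @export
read_microdata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "", comment.char = "#")
  if (nrow(raw) == 0) stop("empty microdata file: ", path, call. = FALSE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(MICRODATA_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("microdata file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tally <- stats::setNames(integer(length(MICRODATA_COLUMNS)), MICRODATA_COLUMNS)
  out <- list()
  for (col in MICRODATA_COLUMNS) {
    rule <- .MICRODATA_RULES[[col]]
    x <- raw[[col]]
    was_na <- is.na(x)
    if (rule$type == "character") {
      out[[col]] <- x
      next
    }
    v <- if (rule$type == "flag") {
      ifelse(tolower(x) %in% c("1", "true"), 1,
             ifelse(tolower(x) %in% c("0", "false"), 0, NA))
    } else {
      suppressWarnings(as.numeric(x))
    }
    if (rule$type == "integer") v[!is.na(v) & v != round(v)] <- NA
    if (!is.null(rule$min)) v[!is.na(v) & v < rule$min] <- NA
    if (!is.null(rule$max)) v[!is.na(v) & v > rule$max] <- NA
    tally[[col]] <- sum(is.na(v) & !was_na)
    out[[col]] <- if (rule$type == "integer") as.integer(v) else v
  }
  bad <- tally[tally > 0]
  if (length(bad)) {
    warning("coerced to missing: ",
            paste(sprintf("%s (%d)", names(bad), bad), collapse = ", "),
            call. = FALSE)
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(df, "coercion_tally") <- tally
  df
}

#' Write respondent microdata as delimited text
#'
#' Plain CSV with empty strings for missing values; round-trips through
#' [read_microdata()].
#'
#' @param records microdata data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(records, path) {
  stopifnot_microdata(records)
  utils::write.csv(records[MICRODATA_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Load the packaged printed index table
#'
#' The 49-row state table of published RHWDI and HWDI values and magnitude
#' rankings (Michigan and South Dakota absent), with the negativity
#' footnote transcribed as a boolean column. Serves as the regression
#' baseline for the concordance module.
#'
#' @param path CSV path; defaults to the packaged copy.
#' @return data.frame with columns `state`, `rhwdi`, `rhwdi_negative`,
#'   `rhwdi_rank`, `hwdi`, `hwdi_rank`; both rank columns validated as
#'   bijections onto 1..n.
#' @export
load_index_fixture <- function(path = system.file("extdata",
                                                  "table2_index_rankings.csv",
                                                  package = "hwdisparity")) {
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("state", "rhwdi", "rhwdi_negative", "rhwdi_rank", "hwdi",
                "hwdi_rank")
  if (!all(required %in% names(fx))) {
    stop("fixture must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  check_rank_bijection(fx$rhwdi_rank, "rhwdi_rank")
  check_rank_bijection(fx$hwdi_rank, "hwdi_rank")
  fx
}

#' Concordance report from a printed index table
#'
#' Computes the full concordance report from the two rank columns of an
#' index fixture (RHWDI ranking vs HWDI ranking).
#'
#' @param fixture a table from [load_index_fixture()] (or of the same
#'   shape).
#' @param top_k largest rank differences to list.
#' @param m_comparisons Bonferroni family size.
#' @return an `hwd_concordance_report`.
#' @export
compare_fixture <- function(fixture = load_index_fixture(), top_k = 5,
                            m_comparisons = 1) {
  concordance_report(fixture$rhwdi_rank, fixture$hwdi_rank, fixture$state,
                     m_comparisons = m_comparisons, top_k = top_k)
}

#' Pipeline configuration
#'
#' @param input microdata source: a data.frame, a CSV path, or a
#'   [generator_config()] (the population is then generated at run time).
#' @param guidelines poverty-guideline table or CSV path (default: the
#'   packaged 2016 table).
#' @param imputation an [imputation_spec()].
#' @param missingness optional [missingness_spec()] applied after
#'   generation (ignored for file/data.frame input).
#' @param weighted_p75 survey-weighted 75th percentile cut point.
#' @param crude_means crude instead of model-adjusted group means.
#' @param at_covariate_means marginal-mean variant flag.
#' @param missing_threshold state-eligibility missingness threshold.
#' @param check_crosstab apply the zero-cell income-by-race eligibility
#'   screen (default `TRUE`).
#' @param m_comparisons,top_k concordance report options.
#' @param output_dir optional directory for delimited-text outputs.
#' @param seed master seed; reseeds the generator and imputation engine.
#' @param log_level one of DEBUG, INFO, WARN, ERROR.
#' @return object of class `hwd_pipeline_config`.
#' @export
pipeline_config <- function(input, guidelines = load_poverty_guidelines(),
                            imputation = imputation_spec(),
                            missingness = NULL,
                            weighted_p75 = FALSE, crude_means = FALSE,
                            at_covariate_means = FALSE,
                            missing_threshold = 0.5, check_crosstab = TRUE,
                            m_comparisons = 1, top_k = 5,
                            output_dir = NULL, seed = 1L,
                            log_level = "INFO") {
  if (is.character(guidelines)) guidelines <- load_poverty_guidelines(guidelines)
  structure(list(input = input, guidelines = guidelines,
                 imputation = imputation, missingness = missingness,
                 weighted_p75 = isTRUE(weighted_p75),
                 crude_means = isTRUE(crude_means),
                 at_covariate_means = isTRUE(at_covariate_means),
                 missing_threshold = missing_threshold,
                 check_crosstab = isTRUE(check_crosstab),
                 m_comparisons = m_comparisons, top_k = top_k,
                 output_dir = output_dir,
                 seed = as_count(seed, "seed", allow_zero = TRUE),
                 log_level = match.arg(log_level, names(.log_levels))),
            class = "hwd_pipeline_config")
}

# Stable 32-bit FNV-1a hash of a serialised R object, for provenance lines.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))[-seq_len(14)]
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full disparity-index pipeline
#'
#' Sequences the analysis end to end: cohort exclusions, state-eligibility
#' screening, per-state chained-equations imputation, income-group
#' classification under both schemes, survey-weighted adjusted group
#' means pooled over imputations, HWDI/RHWDI computation with magnitude
#' ranking, and the rank-concordance report. Identical configuration and
#' seed give identical outputs. States that fail eligibility or
#' imputation are reported, not silently dropped.
#'
#' @param config an [pipeline_config()] object.
#' @return list with `index_table`, `concordance` (NULL with an
#'   explanation in `log` when fewer than 3 computable states), `means`,
#'   `eligibility`, `exclusion_tally`, `dropped_states`, `seed`,
#'   `config_hash`, `log` (character vector of stage messages).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "hwd_pipeline_config")) {
    stop("`config` must come from pipeline_config()", call. = FALSE)
  }
  old <- options(hwdisparity.log_level = config$log_level)
  on.exit(options(old))
  log <- character()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    hwd_log("INFO", "pipeline", "%s", msg)
    log <<- c(log, msg)
  }
  note("seed=%d config_hash=%s", config$seed, config_hash(
    config[setdiff(names(config), "output_dir")]))

  records <- if (inherits(config$input, "hwd_generator_config")) {
    gc <- config$input
    gc$seed <- derive_seed(config$seed, 1L)
    pop <- generate_population(gc)
    if (!is.null(config$missingness)) {
      ms <- config$missingness
      ms$seed <- derive_seed(config$seed, 2L)
      pop <- inject_missingness(pop, ms)
    }
    pop
  } else if (is.character(config$input)) {
    read_microdata(config$input)
  } else {
    stopifnot_microdata(config$input)
  }
  note("input: %d records, %d states", nrow(records),
       length(unique(records$state)))

  excl <- apply_exclusions(records)
  note("exclusions: pregnant=%d age_over_65=%d underweight_bmi=%d retained=%d",
       excl$tally[["pregnant"]], excl$tally[["age_over_65"]],
       excl$tally[["underweight_bmi"]], excl$tally[["retained"]])

  elig <- assess_state_eligibility(excl$records, config$missing_threshold)
  if (!config$check_crosstab) {
    elig$reasons <- sub("^,|,$", "", sub("zero_crosstab_cell", "", elig$reasons))
    elig$eligible <- elig$reasons == ""
  }
  dropped <- elig$state[!elig$eligible]
  for (s in dropped) {
    note("state %s dropped: %s", s, elig$reasons[elig$state == s])
  }
  keep_states <- elig$state[elig$eligible]
  if (!length(keep_states)) stop("no eligible states", call. = FALSE)

  means_list <- list()
  for (s in keep_states) {
    sub <- excl$records[excl$records$state == s, , drop = FALSE]
    spec <- config$imputation
    spec$seed <- derive_seed(config$seed, 100L + match(s, keep_states))
    stack <- tryCatch(impute_chained(sub, spec),
                      hwd_unimputable = function(e) {
                        note("state %s non-computable: %s", s,
                             conditionMessage(e))
                        NULL
                      })
    if (is.null(stack)) {
      dropped <- c(dropped, s)
      next
    }
    means_list[[s]] <- state_group_means(
      stack, config$guidelines, weighted_p75 = config$weighted_p75,
      at_covariate_means = config$at_covariate_means,
      crude = config$crude_means)
  }
  if (!length(means_list)) stop("no computable states", call. = FALSE)
  means <- do.call(rbind, means_list)
  rownames(means) <- NULL

  index_table <- disparity_index_table(means)
  note("indices computed for %d states (%d computable)",
       nrow(index_table), sum(index_table$computable))

  comp <- index_table[index_table$computable, , drop = FALSE]
  concordance <- NULL
  if (nrow(comp) >= 3) {
    concordance <- concordance_report(comp$rhwdi_rank, comp$hwdi_rank,
                                      comp$state,
                                      m_comparisons = config$m_comparisons,
                                      top_k = config$top_k)
  } else {
    note("concordance skipped: only %d computable states (need >= 3)",
         nrow(comp))
  }

  result <- list(index_table = index_table, concordance = concordance,
                 means = means, eligibility = elig,
                 exclusion_tally = excl$tally,
                 dropped_states = unique(dropped), seed = config$seed,
                 config_hash = config_hash(
                   config[setdiff(names(config), "output_dir")]),
                 log = log)
  if (!is.null(config$output_dir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  header <- sprintf("# hwdisparity %s seed=%d config_hash=%s",
                    as.character(utils::packageVersion("hwdisparity")),
                    result$seed, result$config_hash)
  write_with_header <- function(df, file) {
    path <- file.path(config$output_dir, file)
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.csv(df, con, row.names = FALSE, na = "")
    close(con)
  }
  write_with_header(result$index_table, "index_table.csv")
  write_with_header(result$means, "adjusted_means.csv")
  write_with_header(result$eligibility, "state_eligibility.csv")
  write_with_header(data.frame(reason = names(result$exclusion_tally),
                               count = as.integer(result$exclusion_tally)),
                    "exclusion_tally.csv")
  if (!is.null(result$concordance)) {
    x <- result$concordance
    keyvals <- c(
      sprintf("n_states: %d", x$n_states),
      sprintf("rho: %.6f", x$rho),
      sprintf("rho_p_adjusted: %.6f", x$rho_p_adjusted),
      sprintf("bonferroni_m: %d", x$bonferroni_m),
      sprintf("kappa: %.6f", x$kappa),
      sprintf("kappa_p: %.6f", x$kappa_p),
      sprintf("kappa_df: %d", x$kappa_df),
      paste0("counts: ", paste(sprintf("%s=%d", names(x$counts), x$counts),
                               collapse = " "))
    )
    writeLines(c(header, keyvals),
               file.path(config$output_dir, "concordance.txt"))
    tab <- x$diffs
    tab$tercile_a <- x$tercile_a
    tab$tercile_b <- x$tercile_b
    write_with_header(tab[, c("state", "rank_a", "rank_b", "tercile_a",
                              "tercile_b", "diff")], "rank_comparison.csv")
  }
  writeLines(c(header, result$log), file.path(config$output_dir, "run_log.txt"))
  invisible(config$output_dir)
}

#' Command-line entry point
#'
#' Verbs: `simulate` (generator config to microdata CSV), `run-pipeline`
#' (microdata or generator config to index table + concordance report),
#' `compare-indices` (two-rank CSV, default the packaged printed table, to
#' a concordance report). Configuration files are JSON objects whose keys
#' mirror [generator_config()] / [pipeline_config()] argument names.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status 0, invisibly.
#' @export
hwdi_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hwdi <verb> [options]",
    "  simulate        --config cfg.json --out microdata.csv [--seed N]",
    "  run-pipeline    --config cfg.json --out outdir [--seed N]",
    "  compare-indices [--ranks table.csv] [--out report.txt]",
    sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(0L)) }
  verb <- args[1]
  opts <- parse_cli_options(args[-1])
  if (verb == "simulate") {
    cfg <- cli_generator_config(opts)
    pop <- generate_population(cfg)
    if (!is.null(opts$missingness)) pop <- inject_missingness(pop, opts$missingness)
    write_microdata(pop, opts$out %||% stop("--out required", call. = FALSE))
    cat(sprintf("wrote %d records to %s\n", nrow(pop), opts$out))
  } else if (verb == "run-pipeline") {
    raw <- jsonlite::read_json(opts$config %||% stop("--config required",
                                                     call. = FALSE),
                               simplifyVector = TRUE)
    input <- if (is.character(raw$input)) raw$input else {
      do.call(generator_config, raw$generator)
    }
    pc_args <- raw[intersect(names(raw),
                             setdiff(names(formals(pipeline_config)),
                                     c("input", "imputation")))]
    pc_args$input <- input
    if (!is.null(raw$imputation)) {
      pc_args$imputation <- do.call(imputation_spec, as.list(raw$imputation))
    }
    pc_args$output_dir <- opts$out %||% raw$output_dir
    if (!is.null(opts$seed)) pc_args$seed <- as.integer(opts$seed)
    res <- run_pipeline(do.call(pipeline_config, pc_args))
    cat(sprintf("pipeline complete: %d states ranked; outputs in %s\n",
                nrow(res$index_table), pc_args$output_dir %||% "(memory)"))
  } else if (verb == "compare-indices") {
    fx <- if (is.null(opts$ranks)) load_index_fixture() else
      load_index_fixture(opts$ranks)
    rep <- compare_fixture(fx)
    print(rep)
    if (!is.null(opts$out)) {
      sink(opts$out); print(rep); sink()
    }
  } else {
    stop("unknown verb: ", verb, "\n", usage, call. = FALSE)
  }
  invisible(0L)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || i == length(args)) {
      stop("malformed option: ", args[i], call. = FALSE)
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

cli_generator_config <- function(opts) {
  raw <- jsonlite::read_json(opts$config %||% stop("--config required",
                                                   call. = FALSE),
                             simplifyVector = TRUE)
  if (!is.null(raw$household_size_dist)) {
    raw$household_size_dist <- as.data.frame(raw$household_size_dist)
  }
  if (!is.null(opts$seed)) raw$seed <- as.integer(opts$seed)
  do.call(generator_config, raw[intersect(names(raw),
                                          names(formals(generator_config)))])
}
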