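# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so library functions never perturb user-level
#' random streams. Seeds must stay below 2^31 (R integers are 32-bit).
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  seed <- as_count(seed, "seed", allow_zero = TRUE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed; stays within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 7919) %% 2147483647)
}

as_count <- function(x, name, allow_zero = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) ||
      x < if (allow_zero) 0 else 1) {
    stop(sprintf("`%s` must be a single %s integer", name,
                 if (allow_zero) "non-negative" else "positive"), call. = FALSE)
  }
  as.integer(x)
}

check_prob_vector <- function(p, name, n_levels = NULL, tol = 1e-9) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    stop(sprintf("`%s` must be a non-negative numeric probability vector", name),
         call. = FALSE)
  }
  if (!is.null(n_levels) && length(p) != n_levels) {
    stop(sprintf("`%s` must have length %d (got %d)", name, n_levels, length(p)),
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("`%s` must sum to 1 (sum = %.12f)", name, sum(p)), call. = FALSE)
  }
  invisible(p)
}

# Leveled, stage-tagged logging. Level is package-option controlled.
.log_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

hwd_log <- function(level, stage, fmt, ...) {
  threshold <- getOption("hwdisparity.log_level", "INFO")
  if (.log_levels[[level]] < .log_levels[[threshold]]) return(invisible(NULL))
  message(sprintf("%s [%s] (%s) %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, stage, sprintf(fmt, ...)))
  invisible(NULL)
}

# Columns that constitute the analysis variables of a respondent table.
MICRODATA_COLUMNS <- c("state", "age_category", "sex", "race_ethnicity",
                       "education", "income_category", "n_adults", "n_children",
                       "bmi", "pregnant", "survey_weight")

stopifnot_microdata <- function(records, required = MICRODATA_COLUMNS) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data.frame of respondent microdata", call. = FALSE)
  }
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("microdata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(records)
}
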