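# Agreement between the two state rankings: Spearman's rho (Bonferroni-
# adjusted p), Cohen's kappa on tercile labels, and rank-difference
# summaries.

check_rank_bijection <- function(ranks, name) {
  n <- length(ranks)
  if (!n || anyNA(ranks) || !setequal(ranks, seq_len(n))) {
    stop(sprintf("`%s` must be a permutation of 1..n", name), call. = FALSE)
  }
  invisible(as.integer(ranks))
}

#' Spearman rank correlation with Bonferroni adjustment
#'
#' rho is the Pearson correlation of average-tie ranks. The p-value comes
#' from the t approximation with n - 2 degrees of freedom (two-sided),
#' multiplied by the Bonferroni family size `m_comparisons` and capped at
#' 1. For n <= 10 an exact permutation p-value is available (used by
#' oracle tests).
#'
#' @param ranks_a,ranks_b equal-length numeric vectors (ranks or scores),
#'   n >= 3.
#' @param m_comparisons Bonferroni family size (default 1: a single
#'   correlation is tested).
#' @param exact exact permutation null instead of the t approximation;
#'   only permitted for n <= 10.
#' @return list with `rho`, `p_adjusted`, `p_unadjusted`, `n`,
#'   `bonferroni_m`.
#' @export
spearman_with_bonferroni <- function(ranks_a, ranks_b, m_comparisons = 1,
                                     exact = FALSE) {
  n <- length(ranks_a)
  if (length(ranks_b) != n) stop("rank vectors must have equal length",
                                 call. = FALSE)
  if (n < 3) stop("n >= 3 required for the Spearman p-value", call. = FALSE)
  ra <- rank(ranks_a, ties.method = "average")
  rb <- rank(ranks_b, ties.method = "average")
  rho <- stats::cor(ra, rb)
  p <- if (exact) {
    if (n > 10) stop("exact permutation p only supported for n <= 10",
                     call. = FALSE)
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1, function(pm) stats::cor(ra, rb[pm]))
    mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_adjusted = min(1, p * m_comparisons), p_unadjusted = p,
       n = n, bonferroni_m = m_comparisons)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Assign ranking terciles
#'
#' Splits a 1..n ranking into three ordered bins, largest bin first: the
#' first `ceiling(n/3)` ranks are `low`, the remainder is halved with the
#' larger part `middle` and the rest `high` (sizes 17/16/16 at n = 49).
#' The label is monotone in rank.
#'
#' @param ranks a permutation of 1..n.
#' @return character vector of `low`/`middle`/`high` labels.
#' @export
assign_terciles <- function(ranks) {
  ranks <- check_rank_bijection(ranks, "ranks")
  n <- length(ranks)
  s1 <- ceiling(n / 3)
  s2 <- ceiling((n - s1) / 2)
  cut_points <- c(s1, s1 + s2)
  ifelse(ranks <= cut_points[1], "low",
         ifelse(ranks <= cut_points[2], "middle", "high"))
}

#' Cohen's kappa for categorical agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginal products. The p-value is the
#' two-sided large-sample normal test of kappa = 0 using the standard null
#' standard error; `df` is reported as n - 1 (presentation metadata
#' mirroring the field's reporting convention, not a test parameter).
#'
#' @param labels_a,labels_b equal-length label vectors over the same
#'   categories.
#' @param levels category levels; defaults to the sorted union.
#' @return list with `kappa`, `p`, `df`, `n`, `table` (the contingency
#'   table), `degenerate` (TRUE when both labelings are the same constant,
#'   leaving kappa undefined).
#' @export
cohens_kappa <- function(labels_a, labels_b, levels = NULL) {
  n <- length(labels_a)
  if (length(labels_b) != n || !n) {
    stop("label vectors must have equal, positive length", call. = FALSE)
  }
  if (is.null(levels)) levels <- sort(unique(c(labels_a, labels_b)))
  tab <- table(factor(labels_a, levels), factor(labels_b, levels))
  p <- tab / n
  p_o <- sum(diag(p))
  pr <- rowSums(p); pc <- colSums(p)
  p_e <- sum(pr * pc)
  if (1 - p_e < 1e-12) {
    return(list(kappa = NA_real_, p = NA_real_, df = n - 1L, n = n,
                table = tab, degenerate = TRUE))
  }
  kap <- (p_o - p_e) / (1 - p_e)
  # Null (kappa = 0) large-sample SE, Fleiss et al.
  se0 <- sqrt((p_e + p_e^2 - sum(pr * pc * (pr + pc))) / (n * (1 - p_e)^2))
  pval <- if (se0 > 0) 2 * stats::pnorm(-abs(kap / se0)) else NA_real_
  list(kappa = kap, p = pval, df = n - 1L, n = n, table = tab,
       degenerate = FALSE)
}

#' Rank-difference summary between two rankings
#'
#' Per-state absolute rank difference, counts of states with differences
#' of 0, 1, 2, and >= 5, and the `top_k` largest differences (ties broken
#' alphabetically).
#'
#' @param ranks_a,ranks_b permutations of 1..n, aligned by state.
#' @param states state labels.
#' @param top_k how many largest differences to list.
#' @return list with `diffs` (data.frame state/rank_a/rank_b/diff),
#'   `counts` (named: exact_match, diff_eq_1, diff_eq_2, diff_3_to_4,
#'   diff_ge_5), `top` (the top_k rows by descending diff).
#' @export
rank_difference_summary <- function(ranks_a, ranks_b, states, top_k = 5) {
  ranks_a <- check_rank_bijection(ranks_a, "ranks_a")
  ranks_b <- check_rank_bijection(ranks_b, "ranks_b")
  n <- length(ranks_a)
  if (length(states) != n) stop("`states` length mismatch", call. = FALSE)
  d <- abs(ranks_a - ranks_b)
  diffs <- data.frame(state = states, rank_a = ranks_a, rank_b = ranks_b,
                      diff = d)
  counts <- c(exact_match = sum(d == 0), diff_eq_1 = sum(d == 1),
              diff_eq_2 = sum(d == 2), diff_3_to_4 = sum(d %in% 3:4),
              diff_ge_5 = sum(d >= 5))
  top <- diffs[order(-diffs$diff, diffs$state), ][seq_len(min(top_k, n)), ]
  rownames(top) <- NULL
  list(diffs = diffs, counts = counts, top = top)
}

#' Full concordance report between two rankings
#'
#' Combines [spearman_with_bonferroni()], tercile [cohens_kappa()] and
#' [rank_difference_summary()] into one report object.
#'
#' @param ranks_a,ranks_b permutations of 1..n, aligned by state
#'   (conventionally a = RHWDI ranking, b = HWDI ranking).
#' @param states state labels.
#' @param m_comparisons Bonferroni family size.
#' @param top_k largest rank differences to list.
#' @return object of class `hwd_concordance_report`.
#' @export
concordance_report <- function(ranks_a, ranks_b, states, m_comparisons = 1,
                               top_k = 5) {
  ranks_a <- check_rank_bijection(ranks_a, "ranks_a")
  ranks_b <- check_rank_bijection(ranks_b, "ranks_b")
  sp <- spearman_with_bonferroni(ranks_a, ranks_b, m_comparisons)
  ta <- assign_terciles(ranks_a)
  tb <- assign_terciles(ranks_b)
  kp <- cohens_kappa(ta, tb, levels = c("low", "middle", "high"))
  rd <- rank_difference_summary(ranks_a, ranks_b, states, top_k)
  structure(list(
    n_states = length(states),
    rho = sp$rho, rho_p_adjusted = sp$p_adjusted, bonferroni_m = m_comparisons,
    kappa = kp$kappa, kappa_p = kp$p, kappa_df = kp$df,
    tercile_table = kp$table,
    tercile_a = ta, tercile_b = tb,
    diffs = rd$diffs, counts = rd$counts, top = rd$top
  ), class = "hwd_concordance_report")
}

#' @export
print.hwd_concordance_report <- function(x, ...) {
  cat(sprintf("Rank concordance over %d states\n", x$n_states))
  cat(sprintf("  Spearman rho: %.3f (Bonferroni-adjusted p = %.3f, m = %d)\n",
              x$rho, x$rho_p_adjusted, x$bonferroni_m))
  cat(sprintf("  Tercile kappa: %.3f (p = %.3f, df = %d)\n",
              x$kappa, x$kappa_p, x$kappa_df))
  cat("  Rank differences: ",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      "\n", sep = "")
  cat("  Largest differences:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}
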