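#' Two-sided Mann-Whitney U test
#'
#' Tests for a location difference between two samples of per-event
#' scalars. `mode = "exact"` uses the exact null distribution of U when
#' there are no ties, and a full enumeration over all group assignments
#' (midranks for ties) otherwise; `mode = "approx"` uses the tie-corrected
#' normal approximation with continuity correction. `"auto"` picks exact
#' for combined n <= 30 when feasible, approximate otherwise.
#'
#' @param x,y numeric samples (nonempty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return a `stat_result` list: `test = "MWU"`, `statistic` (U for `x`),
#'   `p_value`, `n_per_group`, `mode` actually used.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stopf("both samples must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  enum_size <- choose(m + n, m)
  if (mode == "auto")
    mode <- if ((m + n <= 30 && !has_ties) ||
                (has_ties && enum_size <= 2e5)) "exact" else "approx"
  if (mode == "exact") {
    if (!has_ties) {
      p <- wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
    } else {
      if (enum_size > 2e5)
        stopf("exact mode with ties infeasible for choose(%d, %d) assignments; use mode = 'approx'",
              m + n, m)
      # enumerate all assignments of m ranks to group x
      combs <- utils::combn(m + n, m)
      U_all <- colSums(matrix(r[combs], nrow = m)) - m * (m + 1) / 2
      dev <- abs(U_all - m * n / 2)
      p <- mean(dev >= abs(U - m * n / 2) - 1e-9)
    }
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  structure(list(test = "MWU", statistic = unname(U), p_value = min(p, 1),
                 n_per_group = c(m, n), mode = mode),
            class = "stat_result")
}

#' Kruskal-Wallis rank test across three or more groups
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' `length(groups) - 1` degrees of freedom. For two groups use
#' [mann_whitney_u()].
#'
#' @param groups list of >= 3 nonempty numeric vectors.
#' @return a `stat_result` list: `test = "KW"`, `statistic` (H),
#'   `p_value`, `n_per_group`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 3)
    stopf("kruskal_wallis needs >= 3 groups; use mann_whitney_u for pairs")
  if (any(lengths(groups) == 0)) stopf("all groups must be nonempty")
  kt <- kruskal.test(groups)
  structure(list(test = "KW", statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 n_per_group = lengths(groups)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g, n = %s\n", x$test,
              x$statistic, x$p_value, paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Bonferroni-corrected per-comparison threshold
#'
#' `alpha = fwer / n_comparisons`. Reported values are conventionally
#' rounded to 2 significant figures (e.g. 0.05/30 prints as 0.0017); the
#' full-precision value is what verdicts are compared against.
#'
#' @param fwer family-wise error rate, in (0, 1).
#' @param n_comparisons family size (>= 1).
#' @return the full-precision alpha, with the 2-significant-figure value
#'   attached as attribute `"printed"`.
#' @export
bonferroni_alpha <- function(fwer = 0.05, n_comparisons) {
  if (n_comparisons < 1) stopf("n_comparisons must be >= 1")
  if (fwer <= 0 || fwer >= 1) stopf("fwer must be in (0, 1)")
  a <- fwer / n_comparisons
  attr(a, "printed") <- signif(a, 2)
  a
}

#' Bonferroni comparison family
#'
#' A registered set of `n_comparisons` tests sharing a corrected
#' threshold. The analysis registers one family per figure-style
#' comparison set; sizes follow the study design (see
#' [standard_families()]).
#'
#' @param name family label.
#' @param n_comparisons family size.
#' @param fwer family-wise error rate.
#' @export
bonferroni_family <- function(name, n_comparisons, fwer = 0.05) {
  a <- bonferroni_alpha(fwer, n_comparisons)
  structure(list(name = name, fwer = fwer, n_comparisons = n_comparisons,
                 alpha = as.numeric(a), alpha_printed = attr(a, "printed"),
                 members = list()),
            class = "bonferroni_family")
}

#' The comparison families of the standard analysis
#'
#' Family sizes: Trial-1 two-cohort and three-cohort profiles share n = 10
#' (one test per subset length); per-cohort across-trials Kruskal-Wallis
#' n = 30 (3 cohorts x 10 k); within-Trial-2/3 across-cohorts
#' Kruskal-Wallis n = 20 (2 trials x 10 k); intra-cohort trial-pair
#' Mann-Whitney profiles n = 30 (3 cohorts x 10 k); the all-pairs
#' intra-cohort grid n = 90 (3 cohorts x 3 trial pairs x 10 k); the
#' inter-cohort within-trial grid n = 60 (3 cohort pairs x 2 trials x
#' 10 k).
#'
#' @param fwer family-wise error rate.
#' @return named list of [bonferroni_family()] objects.
#' @export
standard_families <- function(fwer = 0.05) {
  list(trial1_profiles   = bonferroni_family("trial1_profiles", 10, fwer),
       kw_across_trials  = bonferroni_family("kw_across_trials", 30, fwer),
       kw_within_trials  = bonferroni_family("kw_within_trials", 20, fwer),
       trial_pair_mwu    = bonferroni_family("trial_pair_mwu", 30, fwer),
       intra_cohort_grid = bonferroni_family("intra_cohort_grid", 90, fwer),
       inter_cohort_grid = bonferroni_family("inter_cohort_grid", 60, fwer))
}

pool_cell <- function(table, cohort, trial, k) {
  table$value[table$cohort == cohort & table$trial == trial & table$k == k]
}

#' Significance-versus-event-length profile
#'
#' For every subset length `k`, pools per-event values over the
#' comparison's cells (a cell is one cohort x trial pair) and runs the
#' test; the verdict compares the p-value to the family's Bonferroni
#' alpha. Two cells run Mann-Whitney, three or more run Kruskal-Wallis.
#'
#' @param table pooled event-scalar table (baseline- or trial1-normalized,
#'   matching the comparison being made).
#' @param cells list of `list(cohort =, trial =)` specifications.
#' @param family a [bonferroni_family()].
#' @param k_grid subset lengths (default 1-10).
#' @param label comparison label for reporting.
#' @param mode test mode passed to [mann_whitney_u()].
#' @return a `significance_profile` data frame: `k`, `statistic`,
#'   `p_value`, `log10_p`, `alpha`, `significant`; the label, test and
#'   family name are attached as attributes.
#' @export
significance_profile <- function(table, cells, family, k_grid = 1:10,
                                 label = "", mode = "approx") {
  if (length(cells) < 2) stopf("need at least two cells to compare")
  test <- if (length(cells) == 2) "MWU" else "KW"
  rows <- lapply(k_grid, function(k) {
    groups <- lapply(cells, function(cl) pool_cell(table, cl$cohort, cl$trial, k))
    empty <- which(lengths(groups) == 0)
    if (length(empty))
      stopf("comparison '%s': no data for cell %s at k = %g", label,
            paste(sprintf("(%s, trial %d)", cells[[empty[1]]]$cohort,
                          cells[[empty[1]]]$trial), collapse = ","), k)
    res <- if (test == "MWU")
      mann_whitney_u(groups[[1]], groups[[2]], mode = mode)
    else kruskal_wallis(groups)
    data.frame(k = k, statistic = res$statistic, p_value = res$p_value,
               log10_p = log10(res$p_value), alpha = family$alpha,
               significant = res$p_value < family$alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "label") <- label
  attr(out, "test") <- test
  attr(out, "family") <- family$name
  class(out) <- c("significance_profile", "data.frame")
  out
}
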