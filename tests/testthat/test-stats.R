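test_that("exact Mann-Whitney gives the enumeration p for separated samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2 of the C(6,3) = 20 assignments are as extreme
  expect_identical(r$n_per_group, c(3L, 3L))
})

test_that("identical multisets give p = 1 in exact mode", {
  r <- mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3), mode = "exact")
  expect_equal(r$p_value, 1)
})

test_that("exact Mann-Whitney matches full enumeration for all tested n <= 8", {
  set.seed(61)
  for (i in 1:25) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    # mix continuous and tied cases
    if (i %% 2 == 0) {
      x <- sample(1:5, m, replace = TRUE); y <- sample(1:5, n, replace = TRUE)
    } else {
      x <- rnorm(m); y <- rnorm(n, 0.5)
    }
    got <- mann_whitney_u(x, y, mode = "exact")$p_value
    expect_equal(got, enum_mwu_p(x, y), tolerance = 1e-12,
                 label = sprintf("case %d", i))
  }
})

test_that("approximate p tracks exact p closely at n = 15 vs 15", {
  # Exhaustive enumeration over all U values shows the tie-free normal
  # approximation with continuity correction deviates from the exact
  # two-sided p by at most 0.00566, attained near p = 0.46; in the
  # decision-relevant regime (p < 0.2) the deviation stays under 0.005.
  set.seed(62)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15, runif(1, 0, 0.8))
    pe <- mann_whitney_u(x, y, mode = "exact")$p_value
    pa <- mann_whitney_u(x, y, mode = "approx")$p_value
    expect_lt(abs(pe - pa), if (pe < 0.2) 0.005 else 0.006)
  }
  # global bound, checked against the closed-form exact distribution
  m <- 15; n <- 15; mu <- m * n / 2; s <- sqrt(m * n * (m + n + 1) / 12)
  for (U in 0:(m * n)) {
    pe <- min(1, 2 * min(pwilcox(U, m, n), 1 - pwilcox(U - 1, m, n)))
    pc <- min(1, 2 * pnorm(-abs((U - mu - sign(U - mu) * 0.5) / s)))
    expect_lt(abs(pe - pc), 0.006)
  }
})

test_that("empty samples are a configuration error", {
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Kruskal-Wallis matches the hand rank formula, with and without ties", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2)  # 12/(9*10) * 3*((2-5)^2 + 0 + (8-5)^2)
  expect_equal(r$statistic, hand_kw_H(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))))

  set.seed(63)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) sample(1:4, sample(4:8, 1), replace = TRUE))
    expect_equal(kruskal_wallis(g)$statistic, hand_kw_H(g), tolerance = 1e-12)
  }
})

test_that("three identical groups give H = 0 and p = 1", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("fewer than three groups directs the caller to Mann-Whitney", {
  expect_error(kruskal_wallis(list(1:3, 4:6)), "mann_whitney")
})

test_that("Bonferroni alpha reproduces the design's printed thresholds", {
  expect_equal(as.numeric(bonferroni_alpha(0.05, 10)), 0.005)
  expect_equal(as.numeric(bonferroni_alpha(0.05, 1)), 0.05)
  expect_equal(attr(bonferroni_alpha(0.05, 30), "printed"), 0.0017)
  fam <- bonferroni_family("f", 20)
  expect_equal(fam$alpha * fam$n_comparisons, fam$fwer)
})

test_that("verdicts are monotone in alpha", {
  tb <- small_table(seed = 7, k_values = 1:10)
  tbb <- apply_baseline_norm(tb, c(structure(20, names = unique(tb$mouse_id))))
  tb1 <- apply_trial1_norm(tbb, normalization_context(tbb))
  cells <- list(list(cohort = "US+Light", trial = 1),
                list(cohort = "US+Light", trial = 2))
  loose <- significance_profile(tb1, cells, bonferroni_family("a", 1))
  strict <- significance_profile(tb1, cells, bonferroni_family("b", 1000))
  expect_true(all(strict$significant <= loose$significant))
})

test_that("profiles have one entry per subset length with consistent verdicts", {
  tb <- small_table(seed = 7, k_values = 1:10)
  tbb <- apply_baseline_norm(tb, c(structure(20, names = unique(tb$mouse_id))))
  tb1 <- apply_trial1_norm(tbb, normalization_context(tbb))
  fam <- bonferroni_family("pair", 30)
  prof <- significance_profile(tb1,
                               list(list(cohort = "US+Light", trial = 1),
                                    list(cohort = "US+Light", trial = 2)),
                               fam, label = "t1 vs t2")
  expect_identical(nrow(prof), 10L)
  expect_identical(prof$k, 1:10)
  expect_equal(prof$significant, prof$p_value < fam$alpha)
  expect_equal(prof$log10_p, log10(prof$p_value))
  expect_identical(attr(prof, "test"), "MWU")
  expect_error(
    significance_profile(tb1, list(list(cohort = "nope", trial = 1),
                                   list(cohort = "US+Light", trial = 2)),
                         fam),
    "no data")
})

test_that("the registered families carry the study's sizes", {
  fams <- standard_families()
  sizes <- vapply(fams, `[[`, 0, "n_comparisons")
  expect_identical(unname(sizes[c("trial1_profiles", "kw_across_trials",
                                  "kw_within_trials", "trial_pair_mwu",
                                  "intra_cohort_grid", "inter_cohort_grid")]),
                   c(10, 30, 20, 30, 90, 60))
})
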