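test_that("the parametric gate admits normal data and rejects degenerate data", {
  # under a common normal model the conjunction of two Shapiro-Wilk gates
  # and one Levene gate at alpha = 0.05 passes at about 0.95^3 ~ 0.857;
  # bounds are that rate +/- ~2.3 binomial SEs for 100 replicates
  set.seed(220)
  picks <- replicate(100, {
    choose_two_sample_test(rnorm(80), rnorm(80))$choice
  })
  expect_gte(mean(picks == "t_test"), 0.78)
  expect_lte(mean(picks == "t_test"), 0.94)

  # point mass at zero fails Shapiro-Wilk
  expect_equal(choose_two_sample_test(rnorm(30), rep(0, 30))$choice,
               "mann_whitney")

  # symmetry in argument order
  set.seed(41)
  a <- rnorm(40); b <- rnorm(40, 0.3)
  expect_equal(choose_two_sample_test(a, b)$choice,
               choose_two_sample_test(b, a)$choice)

  expect_error(choose_two_sample_test(c(1, 2), rnorm(10)), ">= 3")
})

test_that("two-group comparison reproduces exact toy results", {
  tbl <- data.frame(hf_dwi = c(1, 2, 3, 4, 5, 6) / 10,
                    pGG = c(1, 2, 2, 3, 4, 5))
  # forced Mann-Whitney: complete separation of [1,2,3] vs [4,5,6]
  cmp <- compare_groups(tbl, "pGG_low_vs_high", force_test = "mann_whitney")
  expect_equal(unname(cmp$statistic), 0)   # U = 0
  expect_equal(cmp$p_value, 0.1)           # exact two-sided p, 20 orderings
  expect_equal(cmp$group_medians[["pGG<3"]], 0.2)

  # identical groups under the t branch: statistic 0, p = 1
  tbl2 <- data.frame(hf_dwi = rep(c(0.1, 0.2, 0.3), 2),
                     pTstage = rep(c(2, 3), each = 3))
  cmp2 <- compare_groups(tbl2, "pTstage_2_vs_3", force_test = "t_test")
  expect_equal(unname(cmp2$statistic), 0)
  expect_equal(cmp2$p_value, 1)

  # permutation of rows within groups changes nothing
  set.seed(9)
  tbl3 <- data.frame(hf_dwi = runif(40), pGG = sample(1:5, 40, replace = TRUE))
  c1 <- compare_groups(tbl3, "pGG_low_vs_high")
  c2 <- compare_groups(tbl3[sample(40), ], "pGG_low_vs_high")
  expect_equal(c1$statistic, c2$statistic)
  expect_equal(c1$p_value, c2$p_value)

  expect_error(compare_groups(data.frame(hf_dwi = 1:3, pGG = c(1, 1, 2)),
                              "pTstage_2_vs_3"), "pTstage")
  expect_error(compare_groups(data.frame(hf_dwi = 1:3, pGG = c(1, 2, 2)),
                              "pGG_low_vs_high"), "empty group")
})

test_that("gate override flips the test but not the median direction", {
  set.seed(303)
  tbl <- data.frame(hf_dwi = c(rnorm(50, 0.1, 0.03), rnorm(50, 0.25, 0.03)),
                    pGG = rep(c(2, 4), each = 50))
  gated <- compare_groups(tbl, "pGG_low_vs_high")
  forced <- compare_groups(tbl, "pGG_low_vs_high", force_test = "mann_whitney")
  dir <- function(cmp) sign(cmp$group_medians[[1]] - cmp$group_medians[[2]])
  expect_equal(dir(gated), dir(forced))
})

test_that("Kruskal-Wallis matches the hand-ranked formula and edge cases", {
  # no ties: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 = 32/7
  kw <- kruskal_wallis_by_grade(c(1, 2, 3, 4, 5, 6) / 10,
                                c(1, 1, 2, 2, 3, 3))
  expect_equal(unname(kw$statistic), 32 / 7, tolerance = 1e-12)
  expect_equal(kw$p_value, stats::pchisq(32 / 7, 2, lower.tail = FALSE))

  # all-identical data is H = 0, p = 1, not an error
  kw0 <- kruskal_wallis_by_grade(rep(0.2, 9), rep(1:3, 3))
  expect_equal(unname(kw0$statistic), 0)
  expect_equal(kw0$p_value, 1)

  expect_error(kruskal_wallis_by_grade(1:5 / 10, rep(2, 5)), ">= 2")

  # type-I control under identically distributed groups
  set.seed(71)
  rej <- mean(replicate(200, {
    kruskal_wallis_by_grade(rnorm(60), rep(1:3, each = 20))$p_value < 0.05
  }))
  expect_gte(rej, 0.01); expect_lte(rej, 0.10)
})

test_that("HF-grade correlation behaves across signal, null and sign cases", {
  g <- rep(1:5, each = 10)
  exact <- pearson_hf_vs_grade(0.05 * g, g)
  expect_equal(exact$rho, 1, tolerance = 1e-12)

  anti <- pearson_hf_vs_grade(1 - 0.05 * g + c(0.001, -0.001), g)
  expect_lt(anti$rho, 0)

  set.seed(55)
  small <- replicate(100, {
    abs(pearson_hf_vs_grade(runif(300), sample(1:5, 300, TRUE))$rho) < 0.2
  })
  expect_gte(mean(small), 0.95)

  expect_error(pearson_hf_vs_grade(rep(0.2, 10), rep(1:5, 2)),
               "zero variance")
  expect_error(pearson_hf_vs_grade(runif(10), rep(2, 10)), "zero variance")

  # rank option
  sp <- pearson_hf_vs_grade(exp(0.5 * g), g, method = "spearman")
  expect_equal(sp$rho, 1, tolerance = 1e-12)
})

test_that("two-sided p-values are invariant under group-label swap", {
  set.seed(12)
  tbl <- data.frame(hf_dwi = runif(60), pTstage = rep(c(2, 3), 30))
  swapped <- transform(tbl, pTstage = ifelse(pTstage == 2, 3, 2))
  c1 <- compare_groups(tbl, "pTstage_2_vs_3")
  c2 <- compare_groups(swapped, "pTstage_2_vs_3")
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
})
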