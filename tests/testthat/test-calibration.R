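test_that("propensity model reduces to stratum proportions in toy designs", {
  # identical covariate tables in both cohorts: all distances vanish
  tbl <- make_cohort(n_ref = 6, n_tgt = 6, pGG_ref = rep_len(1:3, 6),
                     pGG_tgt = rep_len(1:3, 6), pT_ref = rep_len(c(2, 3), 6),
                     pT_tgt = rep_len(c(2, 3), 6))
  ps <- fit_propensity(tbl)
  for (s in split(ps$logit, interaction(ps$pGG, ps$pTstage, drop = TRUE)))
    expect_lt(diff(range(s)), 1e-8)

  # covariate independent of cohort: propensity = target proportion
  tbl2 <- make_cohort(n_ref = 20, n_tgt = 20,
                      pGG_ref = rep_len(c(1, 2), 20),
                      pGG_tgt = rep_len(c(1, 2), 20),
                      pT_ref = rep(2, 20), pT_tgt = rep(2, 20))
  ps2 <- fit_propensity(tbl2, covariates = "pGG")
  expect_equal(unique(round(ps2$propensity, 10)), 0.5)

  # 2-stratum toy: saturated logistic fit = empirical stratum proportions
  tbl3 <- make_cohort(n_ref = 40, n_tgt = 40,
                      pGG_ref = rep(c(1, 2), c(10, 30)),
                      pGG_tgt = rep(c(1, 2), c(30, 10)),
                      pT_ref = rep(2, 40), pT_tgt = rep(2, 40))
  ps3 <- fit_propensity(tbl3, covariates = "pGG")
  expect_equal(unname(ps3$propensity[ps3$pGG == 1][1]), 0.75, tolerance = 1e-6)
  expect_equal(unname(ps3$propensity[ps3$pGG == 2][1]), 0.25, tolerance = 1e-6)

  # stratum present in only one cohort triggers the exact-stratum fallback
  tbl4 <- make_cohort(n_ref = 4, n_tgt = 4, pGG_ref = c(1, 1, 2, 2),
                      pGG_tgt = c(1, 1, 1, 3), pT_ref = rep(2, 4),
                      pT_tgt = rep(2, 4))
  expect_warning(fit_propensity(tbl4, covariates = "pGG"), "separation")
})

test_that("optimal matching solves the toy assignments exactly", {
  # exact overlap: zero total distance
  m1 <- optimal_match(c(r1 = 0, r2 = 1), c(t1 = 1, t2 = 0, t3 = 5))
  expect_equal(m1$total_distance, 0)
  expect_equal(m1$pairs$target_patient_id[m1$pairs$reference_patient_id == "r1"], "t2")
  expect_equal(m1$pairs$target_patient_id[m1$pairs$reference_patient_id == "r2"], "t1")

  # nearest of two candidates
  m2 <- optimal_match(c(r1 = 0), c(t1 = 0.4, t2 = 0.3))
  expect_equal(m2$pairs$target_patient_id, "t2")

  # globally optimal, not greedy
  m3 <- optimal_match(c(r1 = 0, r2 = 0.6), c(t1 = 0.1, t2 = 0.5))
  expect_equal(m3$total_distance, 0.2, tolerance = 1e-12)
  expect_equal(m3$total_distance,
               brute_force_assignment(c(0, 0.6), c(0.1, 0.5)),
               tolerance = 1e-12)

  expect_error(optimal_match(c(0, 1), c(0.5)), "infeasible")
})

test_that("matching equals the exhaustive-enumeration minimum (<= 6 refs)", {
  set.seed(990)
  for (k in 1:40) {
    n <- sample(1:6, 1)
    m <- n + sample(0:3, 1)
    ref <- round(rnorm(n), 2)        # rounding induces ties on purpose
    tgt <- round(rnorm(m), 2)
    names(ref) <- sprintf("r%d", seq_len(n))
    names(tgt) <- sprintf("t%d", seq_len(m))
    got <- optimal_match(ref, tgt)
    expect_equal(got$total_distance, brute_force_assignment(ref, tgt),
                 tolerance = 1e-9)
    expect_equal(nrow(got$pairs), n)
    expect_false(anyDuplicated(got$pairs$target_patient_id) > 0)
  }
})

test_that("standardized mean difference matches the hand formula", {
  expect_equal(standardized_mean_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(standardized_mean_difference(c(1, 1, 0, 0), c(1, 0, 0, 0)),
               0.25 / sqrt((1 / 3 + 0.25) / 2), tolerance = 1e-12)
  expect_equal(standardized_mean_difference(c(2, 2), c(2, 2)), 0)  # 0/0 -> 0
  expect_error(standardized_mean_difference(1, c(1, 2)), ">= 2")
})

test_that("matching restores covariate balance on imbalanced cohorts", {
  set.seed(61)
  # target skewed toward low grades, reference balanced
  tbl <- make_cohort(
    n_ref = 40, n_tgt = 120,
    pGG_ref = sample(1:5, 40, replace = TRUE, prob = c(.1, .4, .25, .15, .1)),
    pGG_tgt = sample(1:5, 120, replace = TRUE, prob = c(.35, .4, .15, .06, .04)),
    pT_ref = sample(2:3, 40, replace = TRUE, prob = c(.3, .7)),
    pT_tgt = sample(2:3, 120, replace = TRUE, prob = c(.6, .4)))
  mr <- suppressWarnings(match_cohorts(tbl))
  expect_equal(nrow(mr$pairs), 40)
  expect_lte(max(abs(mr$smd_after)), max(abs(mr$smd_before)))

  # when target counts dominate reference counts in every stratum, the
  # matched marginals reproduce the reference marginals exactly
  tblx <- make_cohort(
    n_ref = 20, n_tgt = 60,
    pGG_ref = rep(c(1, 2, 3), c(5, 10, 5)),
    pGG_tgt = rep(c(1, 2, 3), c(30, 20, 10)),
    pT_ref = rep(2, 20), pT_tgt = rep(2, 60))
  mrx <- suppressWarnings(match_cohorts(tblx, covariates = "pGG"))
  ref_tab <- table(tblx$pGG[tblx$cohort == "reference"])
  matched <- tblx[tblx$patient_id %in% mrx$pairs$target_patient_id, ]
  expect_equal(as.vector(table(matched$pGG)), as.vector(ref_tab))
  expect_equal(max(abs(mrx$smd_after)), 0, tolerance = 1e-12)
})

test_that("median scaling factors follow the definition and its equivariance", {
  mkpool <- function(adc, fbv) data.frame(patient_id = "P", lesion_id = 1L,
                                          adc_mm2_per_s = adc, fbv = fbv)
  # printed-median worked example: 0.70 / 0.84
  ref <- mkpool(c(0.6, 0.7, 0.8) * 1e-3, c(0.1, 0.12, 0.2))
  tgt <- mkpool(c(0.5, 0.84, 1.2) * 1e-3, c(0.05, 0.08, 0.3))
  fac <- compute_scaling_factors(ref, tgt)
  expect_equal(round(fac$f_adc, 2), 0.83)
  expect_equal(fac$f_fbv, 0.12 / 0.08, tolerance = 1e-12)

  expect_equal(unlist(compute_scaling_factors(ref, ref)[c("f_adc", "f_fbv")]),
               c(f_adc = 1, f_fbv = 1))
  tgt2 <- transform(ref, adc_mm2_per_s = adc_mm2_per_s * 2, fbv = fbv * 2)
  expect_equal(compute_scaling_factors(ref, tgt2)$f_adc, 0.5, tolerance = 1e-15)

  expect_error(compute_scaling_factors(ref, mkpool(c(0, 0, 0), c(0, 0, 0))),
               "calibration error")
})

test_that("applying factors equalizes pooled medians and clamps fBV", {
  set.seed(8)
  ref <- data.frame(patient_id = "R", lesion_id = 1L,
                    adc_mm2_per_s = runif(501, 0.3e-3, 1.2e-3),
                    fbv = runif(501, 0.02, 0.4))
  tgt <- data.frame(patient_id = "T", lesion_id = 1L,
                    adc_mm2_per_s = runif(743, 0.4e-3, 1.5e-3),
                    fbv = runif(743, 0.01, 0.3))
  fac <- compute_scaling_factors(ref, tgt)
  scaled <- apply_scaling(tgt, fac, quiet = TRUE)
  expect_equal(median(scaled$adc_mm2_per_s), median(ref$adc_mm2_per_s),
               tolerance = 1e-12)
  expect_equal(median(scaled$fbv), median(ref$fbv), tolerance = 1e-12)

  # identity factors leave the pool untouched
  ident <- structure(list(f_adc = 1, f_fbv = 1), class = "scaling_factors")
  expect_equal(apply_scaling(tgt, ident, quiet = TRUE), tgt)

  # clamp contract
  one <- data.frame(patient_id = "T", lesion_id = 1L,
                    adc_mm2_per_s = 1e-3, fbv = 0.9)
  f154 <- structure(list(f_adc = 1, f_fbv = 1.54), class = "scaling_factors")
  expect_message(out <- apply_scaling(one, f154), "clamped")
  expect_equal(out$fbv, 1)
})

test_that("injected multiplicative center biases are recovered exactly", {
  cfg <- sim_config(n_patients = 15, noise_sigma = 0, seed = 314)
  sim <- sample_cohort(cfg)
  ref <- sim$truth$voxels
  tgt <- apply_center_bias(ref, 1.2, 0.65)
  fac <- compute_scaling_factors(ref, tgt)
  expect_equal(fac$f_adc, 1 / 1.2, tolerance = 1e-12)
  expect_equal(fac$f_fbv, 1 / 0.65, tolerance = 1e-12)
  scaled <- apply_scaling(tgt, fac, quiet = TRUE)
  expect_equal(median(scaled$adc_mm2_per_s), median(ref$adc_mm2_per_s),
               tolerance = 1e-12)
})
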