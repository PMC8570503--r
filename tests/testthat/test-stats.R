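# Variation statistics: relative difference, ICC, Bland-Altman, SDD, and
# the cohort report.

test_that("relative difference: arithmetic, symmetry, scale invariance", {
  expect_equal(relative_difference(80, 120), 40)
  expect_equal(relative_difference(120, 80), 40)
  expect_equal(relative_difference(3.7, 3.7), 0)
  expect_aw_error(relative_difference(1, -1), "aw_undefined_statistic")

  set.seed(8)
  a <- runif(1000, 1, 50); b <- runif(1000, 1, 50)
  s <- runif(1000, 1e-6, 1e6)
  expect_equal(relative_difference(a * s, b * s), relative_difference(a, b),
               tolerance = 1e-12)
})

test_that("ICC variants match an independent reference implementation", {
  # fixture frozen from pingouin.intraclass_corr (ICC1/ICC(A,1)/ICC(C,1))
  t0 <- c(127.419, 88.706, 107.263, 112.657, 108.085, 97.878, 130.23,
          98.107, 140.368, 98.746, 126.097, 145.733)
  t1 <- c(118.308, 88.476, 108.196, 119.745, 107.811, 78.626, 112.706,
          110.668, 139.915, 86.496, 126.722, 157.45)
  expect_equal(icc(t0, t1, "icc2_1")$icc, 0.874684, tolerance = 1e-6)
  expect_equal(icc(t0, t1, "icc3_1")$icc, 0.870169, tolerance = 1e-6)
  expect_equal(icc(t0, t1, "icc1_1")$icc, 0.875008, tolerance = 1e-6)
  expect_equal(icc(t0, t1)$icc_class, "excellent")
})

test_that("ICC degenerate and boundary behavior", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- icc(x, x)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$icc_class, "excellent")

  expect_aw_error(icc(rep(2, 5), rep(2, 5)), "aw_undefined_statistic")
  expect_aw_error(icc(1:3, 1:2), "aw_validation_error")
  expect_aw_error(icc(1, 1), "aw_sample_size_error")

  # boundaries belong to the lower class
  expect_equal(airwaymorph:::icc_class(0.40), "poor")
  expect_equal(airwaymorph:::icc_class(0.75), "fair to good")
  expect_equal(airwaymorph:::icc_class(0.7501), "excellent")
})

test_that("ICC of permuted pairs is zero in expectation", {
  set.seed(99)
  n <- 30
  vals <- replicate(10000, {
    x <- rnorm(n)
    icc(x, sample(x), "icc2_1")$icc
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("ICC recovers planted variance components", {
  set.seed(123)
  sigma_b <- 3; sigma_w <- 2
  n <- 200
  subj <- rnorm(n, 50, sigma_b)
  est <- icc(subj + rnorm(n, 0, sigma_w), subj + rnorm(n, 0, sigma_w))$icc
  expect_lt(abs(est - sigma_b^2 / (sigma_b^2 + sigma_w^2)), 0.05)
})

test_that("Bland-Altman limits and SDD: formulas and antisymmetry", {
  z <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$loa_upper, 0)
  expect_equal(z$loa_lower, 0)
  expect_equal(sdd(c(1, 2, 3), c(1, 2, 3)), 0)

  set.seed(5)
  t0 <- rnorm(20, 100, 10); t1 <- rnorm(20, 100, 10)
  ba <- bland_altman(t0, t1)
  expect_equal(ba$diff_sd, sd(t0 - t1))
  expect_equal(ba$loa_upper, ba$diff_mean + 1.96 * ba$diff_sd)
  # swapping the scans negates and swaps the limits
  ba2 <- bland_altman(t1, t0)
  expect_equal(ba2$loa_upper, -ba$loa_lower)
  expect_equal(ba2$loa_lower, -ba$loa_upper)
  expect_equal(sdd(t0, t1), 1.96 * sd(t0 - t1))

  expect_aw_error(bland_altman(1, 1), "aw_sample_size_error")
  expect_aw_error(sdd(2, 2), "aw_sample_size_error")
})

test_that("cohort report has the canonical 50-row shape and consistency", {
  cohort <- make_paired_cohort(6, seed = 2)
  long <- do.call(rbind, lapply(cohort, function(s) {
    rbind(parameters_to_long(analytic_truth(s$spec_t0), s$subject_id, "T0"),
          parameters_to_long(analytic_truth(s$spec_t1), s$subject_id, "T1"))
  }))
  rep <- summarize_cohort(long)
  expect_s3_class(rep, "variation_report")
  expect_equal(nrow(rep), 50)
  expect_equal(length(unique(rep$parameter)), 10)
  expect_equal(length(unique(rep$region)), 5)
  # limits / SDD internal consistency, exact
  expect_equal(rep$loa_upper - rep$loa_lower, 2 * rep$sdd)
  expect_equal(rep$sdd, 1.96 * rep$diff_sd)
  expect_true(all(is.na(rep$icc) | (rep$icc >= -1 & rep$icc <= 1)))
})

test_that("zero-perturbation cohorts are degenerate in the documented way", {
  spec <- default_phantom_spec(noise_sd = 0)
  tr <- analytic_truth(spec)
  long <- do.call(rbind, lapply(sprintf("S%02d", 1:4), function(id)
    rbind(parameters_to_long(tr, id, "T0"), parameters_to_long(tr, id, "T1"))))
  rep <- summarize_cohort(long)
  expect_equal(rep$rd_mean, rep(0, 50))
  expect_equal(rep$sdd, rep(0, 50))
  # identical scans AND identical subjects: no variance anywhere -> flagged
  expect_true(all(is.na(rep$icc)))
  expect_true(all(rep$icc_class == "undefined"))
})

test_that("missing timepoints are reported by subject", {
  spec <- default_phantom_spec(noise_sd = 0)
  tr <- analytic_truth(spec)
  long <- rbind(parameters_to_long(tr, "S01", "T0"),
                parameters_to_long(tr, "S01", "T1"),
                parameters_to_long(tr, "S02", "T0"))
  expect_error(summarize_cohort(long), "S02", class = "aw_data_error")
})

test_that("area perturbation hits the MCA harder than the length", {
  # minima respond to any local narrowing; plane distances only to jitter
  set.seed(17)
  base <- default_phantom_spec(noise_sd = 0)
  L <- base$axis_length
  wins <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    rd_mca <- rd_len <- numeric(10)
    for (i in 1:10) {
      s0 <- perturb_phantom(base, list(area_scale_amp = 0.25,
                                       landmark_jitter_sd = 2.5,
                                       axis_bend_amp = 0), seed = r * 1000 + i)
      s1 <- perturb_phantom(s0, list(area_scale_amp = 0.15,
                                     landmark_jitter_sd = 1.0,
                                     axis_bend_amp = 0), seed = r * 1000 + 500 + i)
      tg <- seq(0, L, length.out = 2049)
      mca0 <- min(s0$area_profile(tg)); mca1 <- min(s1$area_profile(tg))
      len0 <- s0$landmark_fracs[["BEP"]] * L
      len1 <- s1$landmark_fracs[["BEP"]] * L
      rd_mca[i] <- relative_difference(mca0, mca1)
      rd_len[i] <- relative_difference(len0, len1)
    }
    if (mean(rd_mca) > mean(rd_len)) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.95)
})
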