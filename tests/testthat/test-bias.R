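test_that("beta equation matches hand-substitution and its symmetries", {
  ref1 <- mk_fit(100, -9); ref2 <- mk_fit(100, -9)
  # self-reference is exactly zero
  expect_identical(biasFactor(ref1, ref2, ref1, ref2), 0)
  # worked oracle: halved arrestin Emax => beta = log10(2)
  lig2 <- mk_fit(50, -9)
  expect_equal(biasFactor(ref1, lig2, ref1, ref2), log10(2),
               tolerance = 1e-12)
  # pathway swap negates beta
  lig1 <- mk_fit(80, -8.5)
  b <- biasFactor(lig1, lig2, ref1, ref2)
  expect_equal(biasFactor(lig2, lig1, ref2, ref1), -b, tolerance = 1e-12)
  # role exchange negates beta
  expect_equal(biasFactor(ref1, ref2, lig1, lig2), -b, tolerance = 1e-12)
  # common Emax rescaling in one pathway cancels
  b2 <- biasFactor(mk_fit(80 * 7, -8.5), lig2, mk_fit(100 * 7, -9), ref2)
  expect_equal(b2, b, tolerance = 1e-12)
  # common EC50 unit change cancels
  b3 <- biasFactor(mk_fit(80, -8.5 + 3), mk_fit(50, -9 + 3),
                   mk_fit(100, -9 + 3), mk_fit(100, -9 + 3))
  expect_equal(b3, b, tolerance = 1e-12)
  # guard rails
  expect_error(biasFactor(mk_fit(-5, -9), lig2, ref1, ref2), "Emax")
  expect_error(biasFactor(mk_fit(80, -9, converged = FALSE), lig2,
                          ref1, ref2), "converge")
})

sim_fits <- function(seed, noise_sd = 5, n = 8,
                     lig_arr_emax = 50) {
  profs <- list(
    LigandProfile("ref", list(
      gi_dissociation = c(emax = 100, baseline = 0, log10_ec50 = -9,
                          hill = 1),
      arrestin_recruitment = c(emax = 100, baseline = 0, log10_ec50 = -9,
                               hill = 1))),
    LigandProfile("lig", list(
      gi_dissociation = c(emax = 100, baseline = 0, log10_ec50 = -9,
                          hill = 1),
      arrestin_recruitment = c(emax = lig_arr_emax, baseline = 0,
                               log10_ec50 = -9, hill = 1))))
  panel <- simulatePanel(profs, config = SimulationConfig(
    noise_sd = noise_sd, n_experiments = n, seed = seed))
  fitDoseResponse(panel, pooling = "per_experiment")
}

test_that("per-experiment bias summarizes matched experiments", {
  fits <- sim_fits(seed = 101L)
  res <- perExperimentBias(fits, "lig", "ref")
  expect_length(res@per_experiment_betas, 8L)
  expect_equal(res@mean, mean(res@per_experiment_betas))
  # reference against itself: all betas exactly zero, balanced
  self <- perExperimentBias(fits, "ref", "ref")
  expect_identical(unname(self@per_experiment_betas), rep(0, 8))
  expect_identical(self@sem, 0)
  expect_identical(self@classification, "balanced")
  # unmatched experiment ids are an explicit error
  broken <- fits[!vapply(fits, function(f)
    f@ligand == "lig" && f@pathway == "arrestin_recruitment" &&
      identical(f@experiment, "3"), logical(1))]
  expect_error(perExperimentBias(broken, "lig", "ref"), "3")
})

test_that("simulated panels recover the true beta", {
  # true beta = log10(100/50) ~ 0.301; check mean within 3 sem across seeds
  hits <- vapply(1:20, function(s) {
    res <- perExperimentBias(sim_fits(seed = s), "lig", "ref")
    abs(res@mean - log10(2)) <= 3 * res@sem
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("many-vs-one comparison controls errors and detects shifts", {
  set.seed(42)
  # type-I: all groups from one distribution; few rejections expected
  false_pos <- vapply(1:100, function(i) {
    groups <- lapply(1:4, function(g) rnorm(8, 0, 0.2))
    names(groups) <- c("ref", "a", "b", "c")
    any(compareVsReference(groups, "ref")@p_values < 0.05)
  }, logical(1))
  expect_lte(mean(false_pos), 0.10)
  # power: one group offset by 5 pooled sd
  set.seed(43)
  groups <- lapply(1:4, function(g) rnorm(8, 0, 0.2))
  names(groups) <- c("ref", "a", "b", "c")
  groups$c <- groups$c + 5 * 0.2
  cmp <- compareVsReference(groups, "ref")
  expect_lt(cmp@p_values[["c"]], 0.001)
  expect_s4_class(cmp, "BiasComparison")
  expect_error(compareVsReference(list(ref = rnorm(4), a = 0.5), "ref"),
               ">= 2 observations")
})

test_that("two-group t-test matches the closed-form oracle", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # closed-form pooled t: t = (1-4... ) => -3.674, p = 0.0213
  cmp <- compareTwo(a, b)
  expect_equal(unname(cmp@statistic), -3.674, tolerance = 1e-3)
  expect_equal(unname(cmp@p_values), 0.02131, tolerance = 1e-3)
  # identical groups: t = 0, p = 1
  same <- compareTwo(a, a)
  expect_equal(unname(same@statistic), 0)
  expect_equal(unname(same@p_values), 1)
  # degenerate variance with unequal means -> p = 0 with warning
  expect_warning(z <- compareTwo(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_equal(unname(z@p_values), 0)
  # ANOVA on two groups agrees with the two-sample test
  cmp2 <- compareVsReference(list(ref = a, b = b, b2 = b), "ref",
                             adjust = "none")
  expect_equal(unname(cmp2@p_values[["b"]]),
               unname(compareTwo(b, a)@p_values), tolerance = 0.05)
})

test_that("preset end-to-end: shortest truncations are G-protein biased", {
  panel <- simulatePanel(generatePanel("ccl15_truncations"),
                         config = SimulationConfig(n_experiments = 8,
                                                   noise_sd = 5, seed = 7L))
  norm <- normalizePanel(panel, "reference_max_100",
                         reference = "CCL15(27-92)")
  fits <- fitDoseResponse(norm, pooling = "per_experiment")
  # mean bias is positive for every shortest truncation; significance of the
  # one-sample test at n = 8 is noise-realization dependent, so only a
  # sign-flipped classification would be an error
  short <- c("CCL15(29-92)", "CCL15(30-92)", "CCL15(31-92)")
  for (lig in short) {
    res <- perExperimentBias(fits, lig, "CCL15(27-92)")
    expect_gt(res@mean, 0)
    expect_true(res@classification %in% c("gi_biased", "balanced"))
  }
})
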