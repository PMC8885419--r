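make_panel <- function(noise_sd = 0, n = 2, seed = 1L,
                       params = c(emax = 80, baseline = 5,
                                  log10_ec50 = -9.2, hill = 1)) {
  prof <- LigandProfile("lig", list(gi_dissociation = params))
  simulateExperiment(prof, "gi_dissociation",
                     SimulationConfig(noise_sd = noise_sd, n_experiments = n,
                                      seed = seed))
}

test_that("normalization conventions behave as documented", {
  panel <- make_panel(noise_sd = 2, n = 3, seed = 11L)
  norm <- normalizePanel(panel, "reference_max_100", reference = "lig")
  expect_equal(max(records(norm)$response), 100)
  expect_identical(norm@normalization, "reference_max_100")
  # a trace identical to the reference maps onto it exactly
  df2 <- records(panel)
  clone <- df2; clone$ligand <- "clone"
  both <- new("DoseResponsePanel", records = rbind(df2, clone))
  nb <- records(normalizePanel(both, "reference_max_100", reference = "lig"))
  expect_equal(nb$response[nb$ligand == "clone"],
               nb$response[nb$ligand == "lig"])
  # constant trace under fold_over_lowest_dose -> all 100
  const <- new("DoseResponsePanel", records = data.frame(
    ligand = "c", pathway = "camp", experiment = "1",
    concentration_M = 10^seq(-13, -6), response = 42))
  expect_true(all(records(normalizePanel(const,
                                         "fold_over_lowest_dose"))$response
                  == 100))
  # missing lowest-dose anchor is an identified error
  holey <- new("DoseResponsePanel", records = rbind(
    data.frame(ligand = "a", pathway = "camp", experiment = "1",
               concentration_M = 10^seq(-13, -6), response = 1),
    data.frame(ligand = "b", pathway = "camp", experiment = "1",
               concentration_M = 10^seq(-12, -6), response = 1)))
  expect_error(normalizePanel(holey, "fold_over_lowest_dose"), "b")
  # untreated control maps to 100
  endo <- new("DoseResponsePanel", records = rbind(
    data.frame(ligand = "untreated", pathway = "endocytosis",
               experiment = "1", concentration_M = 1e-13, response = 50),
    data.frame(ligand = "lig", pathway = "endocytosis", experiment = "1",
               concentration_M = 10^seq(-12, -6), response = 25)))
  ne <- records(normalizePanel(endo, "untreated_100",
                               reference = "untreated"))
  expect_equal(ne$response[ne$ligand == "untreated"], 100)
  expect_equal(unique(ne$response[ne$ligand == "lig"]), 50)
  expect_error(normalizePanel(panel, "reference_max_100"), "reference")
})

test_that("noiseless data recover generating parameters exactly", {
  for (model in c("hill_fixed_1", "hill_free")) {
    fit <- fitDoseResponse(make_panel(), model = model)[[1]]
    expect_true(converged(fit))
    est <- estimates(fit)
    expect_equal(est[["baseline"]], 5, tolerance = 1e-6)
    expect_equal(est[["emax"]], 80, tolerance = 1e-6)
    expect_equal(est[["log10_ec50"]], -9.2, tolerance = 1e-6)
  }
})

test_that("flat data are flagged degenerate, not fitted", {
  flat <- new("DoseResponsePanel", records = data.frame(
    ligand = "flat", pathway = "camp", experiment = "1",
    concentration_M = 10^seq(-13, -6), response = 0))
  fit <- fitDoseResponse(flat)[[1]]
  expect_true(fit@degenerate)
  expect_true(is.na(estimates(fit)[["log10_ec50"]]))
  expect_error(biasFactor(fit, fit, fit, fit), "degenerate")
})

test_that("fits are invariant to record order and equivariant to scaling", {
  panel <- make_panel(noise_sd = 5, n = 4, seed = 21L)
  fit1 <- fitDoseResponse(panel)[[1]]
  shuf <- records(panel)[sample(nrow(records(panel))), ]
  fit2 <- fitDoseResponse(new("DoseResponsePanel", records = shuf))[[1]]
  expect_equal(estimates(fit1), estimates(fit2), tolerance = 1e-8)
  scaled <- records(panel); scaled$response <- scaled$response * 3
  fit3 <- fitDoseResponse(new("DoseResponsePanel", records = scaled))[[1]]
  expect_equal(estimates(fit3)[["emax"]], 3 * estimates(fit1)[["emax"]],
               tolerance = 1e-6)
  expect_equal(estimates(fit3)[["log10_ec50"]],
               estimates(fit1)[["log10_ec50"]], tolerance = 1e-6)
})

test_that("fixed-slope and free-slope fits agree on hill = 1 data", {
  panel <- make_panel(noise_sd = 3, n = 6, seed = 31L)
  f1 <- estimates(fitDoseResponse(panel, model = "hill_fixed_1")[[1]])
  f2 <- estimates(fitDoseResponse(panel, model = "hill_free")[[1]])
  expect_equal(f2[["hill"]], 1, tolerance = 0.2)
  expect_equal(f1[["log10_ec50"]], f2[["log10_ec50"]], tolerance = 0.1)
})

test_that("per-experiment pooling returns one fit per experiment", {
  panel <- make_panel(noise_sd = 3, n = 4, seed = 41L)
  fits <- fitDoseResponse(panel, pooling = "per_experiment")
  expect_length(fits, 4L)
  expect_setequal(vapply(fits, function(f) f@experiment, character(1)),
                  as.character(1:4))
  expect_error(fitDoseResponse(new("DoseResponsePanel", records =
    data.frame(ligand = "x", pathway = "camp", experiment = "1",
               concentration_M = c(1e-9, 1e-8, 1e-7), response = 1:3))),
    "4 distinct concentrations")
})
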