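test_that("buildModel validates referential integrity and basic invariants", {
  m <- buildModel("minimal", rbind(speciesSpec("A", 10)),
                  list(reactionSpec(character(0), "A", "k")), c(k = 1e-3))
  expect_s4_class(m, "KineticModel")
  expect_identical(speciesNames(m), "A")

  expect_error(
    buildModel("bad", rbind(speciesSpec("A", 10)),
               list(reactionSpec("X", character(0), "k")), c(k = 1e-3)),
    "unknown species")
  expect_error(
    buildModel("dup", rbind(speciesSpec("A", 1), speciesSpec("A", 2)),
               list(reactionSpec("A", character(0), "k")), c(k = 1)),
    "duplicate")
  expect_error(
    buildModel("neg", rbind(speciesSpec("A", -1)),
               list(reactionSpec("A", character(0), "k")), c(k = 1)),
    "non-negative")
  expect_error(
    buildModel("zerorate", rbind(speciesSpec("A", 1)),
               list(reactionSpec("A", character(0), "k")), c(k = 0)),
    "positive")
  expect_error(
    buildModel("none", rbind(speciesSpec("A", 1)), list(), numeric(0)),
    "at least one reaction")
  expect_error(
    buildModel("order3", rbind(speciesSpec("A", 9)),
               list(reactionSpec(c("A", "A", "A"), character(0), "k")),
               c(k = 1)),
    "order")
})

test_that("the TGF-beta model exposes the active/inactive ligand pools and the repression complex", {
  m <- buildTgfbSmad3Model("with_miR140")
  expect_true(all(c("TGFb_A", "TGFb_I", "miR140_SMAD3mRNA")
                  %in% speciesNames(m)))
  ic <- initialCounts(m)
  expect_equal(unname(ic["miR140"]), 500)
  expect_equal(unname(rateValues(m)["k_synmiR140"]), 0.0018)
})

test_that("calibration helpers implement the half-life-first recipe", {
  expect_identical(steadyStateSynthesisRate(1e-4, 100), 0.01)
  expect_identical(steadyStateSynthesisRate(1e-4, 0), 0)
  expect_error(steadyStateSynthesisRate(0, 10), "kDeg")
  expect_error(steadyStateSynthesisRate(1e-4, -1), "targetLevel")

  expect_equal(halfLifeToRate(log(2)), 1.0)
  expect_equal(halfLifeToRate(3600), log(2) / 3600)  # ~1.925e-4
  expect_error(halfLifeToRate(0), "halfLife")

  # round trips to machine precision
  expect_equal(log(2) / halfLifeToRate(53.47 * 3600), 53.47 * 3600)
  expect_equal(steadyStateSynthesisRate(halfLifeToRate(3600), 250) /
                 halfLifeToRate(3600), 250)
})

test_that("a birth-death process settles at k_syn / k_deg (inverse calibration)", {
  # k_syn = 0.0018 with steady state 500 implies k_deg = 3.6e-6
  kDeg <- 0.0018 / 500
  expect_equal(kDeg, 3.6e-6)
  m <- birthDeathModel(kSyn = 0.0018, kDeg = kDeg, x0 = 500)
  es <- runEnsemble(m, nReps = 60, duration = 2e5, nIntervals = 50,
                    baseSeed = 5)
  final <- ensembleMean(es)[51, "A"]
  se <- 3 * sqrt(500 / 60)  # Poisson variance, 3 SEs
  expect_lt(abs(final - 500), se)
})

test_that("interventions override, compose, and leave the input untouched", {
  m <- buildIl1Mmp13Model("with_miR140")
  iv <- intervention("halve miR-140 synthesis",
                     rateOverrides = c(k_synmiR140 = 0.0009))
  m2 <- applyIntervention(m, iv)
  expect_equal(unname(rateValues(m2)["k_synmiR140"]), 0.0009)
  expect_equal(unname(rateValues(m)["k_synmiR140"]), 0.0018)  # original intact
  others <- setdiff(names(rateValues(m)), "k_synmiR140")
  expect_identical(rateValues(m2)[others], rateValues(m)[others])

  # idempotence and composition
  expect_identical(rateValues(applyIntervention(m2, iv)), rateValues(m2))
  ivA <- intervention("a", initialOverrides = c(miR140 = 100))
  ivB <- intervention("b", rateOverrides = c(k_actNFkB = 1e-4))
  ivAB <- intervention("ab", initialOverrides = c(miR140 = 100),
                       rateOverrides = c(k_actNFkB = 1e-4))
  seq2 <- applyIntervention(applyIntervention(m, ivA), ivB)
  once <- applyIntervention(m, ivAB)
  expect_identical(initialCounts(seq2), initialCounts(once))
  expect_identical(rateValues(seq2), rateValues(once))

  # identity and error cases
  m3 <- applyIntervention(m, intervention("empty"))
  expect_identical(initialCounts(m3), initialCounts(m))
  expect_identical(rateValues(m3), rateValues(m))
  expect_error(applyIntervention(m, intervention("x",
                 initialOverrides = c(NOPE = 1))), "unknown species")
  expect_error(applyIntervention(m, intervention("x",
                 rateOverrides = c(k_nope = 1))), "unknown rate")

  # zero synthesis produces the miR-140-null model
  null <- applyIntervention(m, intervention("null",
            initialOverrides = c(miR140 = 0),
            rateOverrides = c(k_synmiR140 = 0)))
  expect_equal(unname(initialCounts(null)["miR140"]), 0)
  expect_false("k_synmiR140" %in% names(rateValues(null)))
})

test_that("calibrateModel recovers a known degradation rate from its steady state", {
  truth <- 2e-4
  m <- birthDeathModel(kSyn = 0.02, kDeg = 5e-5, x0 = 0)  # wrong k_deg
  con <- calibrationConstraint("A", "value_at_time", time = 2e5,
                               target = 0.02 / truth, tolerance = 0.05)
  fit <- calibrateModel(m, list(con), freeParams = "k_deg",
                        lower = 1e-6, upper = 1e-2, seed = 3)
  expect_equal(unname(rateValues(fit)["k_deg"]), truth, tolerance = 0.05)
  expect_s3_class(attr(fit, "calibration"), "data.frame")

  # an already-satisfying model is returned unchanged
  m0 <- birthDeathModel(kSyn = 0.02, kDeg = truth, x0 = 0)
  fit0 <- calibrateModel(m0, list(con), freeParams = "k_deg",
                         lower = 1e-6, upper = 1e-2, seed = 3)
  expect_identical(rateValues(fit0), rateValues(m0))

  # impossible constraint reports residuals instead of failing silently
  bad <- calibrationConstraint("A", "value_at_time", time = 2e5,
                               target = 1e9, tolerance = 0.01)
  expect_error(calibrateModel(m, list(bad), freeParams = "k_deg",
                              lower = 1e-6, upper = 1e-2, seed = 3,
                              nSamples = 10),
               "calibration failed")
})
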